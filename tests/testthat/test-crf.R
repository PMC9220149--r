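test_that("path scores sum emissions and transitions, including START/STOP", {
  em <- matrix(c(1, 2), nrow = 1) # length-1 sequence, 2 tags
  tr <- matrix(0, 4, 4)
  expect_equal(crf_score(em, tr, 2L), 2.0)
  expect_equal(crf_score(em, tr, 1L), 1.0)

  em2 <- matrix(0, 3, 2)
  expect_equal(crf_score(em2, tr, c(1L, 2L, 1L)), 0)

  tr2 <- matrix(0, 4, 4)
  tr2[3, 2] <- 1.5
  tr2[2, 4] <- 0.25  # tag 2 -> STOP
  expect_equal(crf_score(em, tr2, 2L), 2 + 1.5 + 0.25)

  expect_error(crf_score(em2, tr2, c(1L, 2L)), "length")
})

test_that("a path crossing a masked BIO transition scores -Inf", {
  tagset <- c("O", "B-SIZE", "I-SIZE")
  mask <- bio_transition_mask(tagset)
  em <- matrix(0, 2, 3)
  expect_equal(crf_score(em, mask, c(1L, 3L)), -Inf) # O -> I-SIZE
  expect_equal(crf_score(em, mask, c(2L, 3L)), 0)    # B-SIZE -> I-SIZE
  expect_error(crf_nll(em, mask, c(1L, 3L)), "forbidden")
})

test_that("log-partition matches closed forms on uniform instances", {
  tr <- matrix(0, 4, 4)
  expect_equal(crf_log_partition(matrix(0, 1, 2), tr), log(2))
  expect_equal(crf_log_partition(matrix(0, 2, 2), tr), log(4))
  # uniform scores, 2 tags, length 1: nll of either path is log 2
  expect_equal(crf_nll(matrix(0, 1, 2), tr, 1L), log(2))
})

test_that("nll is zero when only one path is possible", {
  # mask everything except the single path START -> 1 -> 1 -> STOP
  tr <- matrix(-Inf, 4, 4)
  tr[3, 1] <- 0; tr[1, 1] <- 0; tr[1, 4] <- 0
  em <- matrix(runif(6), 3, 2)
  expect_equal(crf_nll(em, tr, c(1L, 1L, 1L)), 0)
})

test_that("score, partition and decoding agree with exhaustive enumeration", {
  withr::local_seed(13)
  for (rep in 1:40) {
    n_pos <- sample(1:6, 1)
    n_tags <- sample(2:5, 1)
    inst <- random_crf_instance(n_pos, n_tags)
    expect_equal(crf_log_partition(inst$emissions, inst$transitions),
                 enum_log_partition(inst$emissions, inst$transitions),
                 tolerance = 1e-6)
    path <- viterbi_decode(inst$emissions, inst$transitions)
    expect_equal(crf_score(inst$emissions, inst$transitions, path),
                 enum_best_score(inst$emissions, inst$transitions),
                 tolerance = 1e-6)
  }
  # the spec'd fixed case: random 3x4 instance under seed 13
  withr::local_seed(13)
  inst <- random_crf_instance(3, 4, mask_some = FALSE)
  expect_equal(crf_log_partition(inst$emissions, inst$transitions),
               enum_log_partition(inst$emissions, inst$transitions),
               tolerance = 1e-6)
})

test_that("path probabilities normalize to one", {
  withr::local_seed(29)
  tagset <- c("O", "B-SIZE", "I-SIZE")
  tr <- bio_transition_mask(tagset) +
    matrix(runif(25, -1, 1), 5, 5)
  em <- matrix(runif(9, -1, 1), 3, 3)
  paths <- enum_paths(3, 3)
  probs <- apply(paths, 1, function(p) {
    s <- crf_score(em, tr, p)
    if (!is.finite(s)) return(0)
    exp(-crf_nll(em, tr, p))
  })
  expect_equal(sum(probs), 1, tolerance = 1e-6)
})

test_that("decoded paths never violate the BIO mask", {
  withr::local_seed(41)
  tagset <- nodule_tagset()
  mask <- bio_transition_mask(tagset)
  k <- length(tagset)
  for (rep in 1:25) {
    n_pos <- sample(1:12, 1)
    em <- matrix(runif(n_pos * k, -3, 3), n_pos, k)
    tr <- mask + matrix(runif((k + 2)^2, -1, 1), k + 2, k + 2)
    tr[!is.finite(mask)] <- -Inf
    path <- viterbi_decode(em, tr)
    tags <- tagset[path]
    expect_null(noduleaudit:::bio_violation(tags, tagset))
  }
})

test_that("exact ties break toward the lowest tag index", {
  em <- matrix(0, 4, 3)
  tr <- matrix(0, 5, 5)
  expect_equal(viterbi_decode(em, tr), rep(1L, 4))
})
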