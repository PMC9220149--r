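test_that("corpus generation is deterministic and validates n", {
  a <- generate_corpus(30, seed = 42)
  b <- generate_corpus(30, seed = 42)
  expect_identical(a$reports, b$reports)
  expect_identical(a$annotations, b$annotations)
  expect_identical(a$gold, b$gold)
  expect_error(generate_corpus(0, seed = 1), "n must be")
})

test_that("state sampling recovers a configured categorical distribution", {
  w <- list(p_absent = 0,
            levels = tibble::tibble(level = c("L1", "L3", "L5", "L7"),
                                    weight = rep(0.25, 4)))
  st <- sample_states(10000, weights = w, seed = 8)
  freq <- table(st$gold_level) / nrow(st)
  sd3 <- 3 * sqrt(0.25 * 0.75 / nrow(st))
  expect_true(all(abs(freq - 0.25) < sd3))

  # a degenerate distribution always yields its single state
  w1 <- list(p_absent = 0,
             levels = tibble::tibble(level = "L2", weight = 1))
  st1 <- sample_states(50, weights = w1, seed = 9)
  expect_true(all(st1$solidity == "SOLID" & st1$size_bin == "LT6" &
                    st1$risk == "HIGH"))
  expect_identical(sample_states(3, seed = 5), sample_states(3, seed = 5))
})

test_that("gold levels equal the oracle recommendation for every report", {
  corp <- generate_corpus(300, seed = 77)
  expect_equal(oracle_recommend(corp$gold), corp$gold$gold_level)
  # size bins are consistent with sampled sizes
  pres <- corp$gold[corp$gold$present, ]
  expect_equal(assign_size_bin(pres$size_mm, pres$solidity), pres$size_bin)
})

test_that("gold BIO spans reproduce vocabulary surface forms", {
  corp <- tiny_corpus()
  vocab <- default_vocabulary()
  mentions <- gold_mentions(corp)
  key <- function(x) {
    vapply(x, function(s) paste(tolower(tokenize_text(s)$token),
                                collapse = " "), "")
  }
  vocab_keys <- paste(vocab$type, key(vocab$surface))
  non_size <- mentions[mentions$type != "SIZE", ]
  expect_true(all(paste(non_size$type, key(non_size$text)) %in% vocab_keys))
  # every size mention parses to a positive size
  expect_true(all(parse_size_mm(mentions$text[mentions$type == "SIZE"]) > 0))
  # spans index the rendered text correctly (offsets are 0-based,
  # end-exclusive into findings + " " + impression)
  full <- paste(corp$reports$findings, corp$reports$impression)
  names(full) <- corp$reports$report_id
  extracted <- substr(full[mentions$report_id], mentions$start + 1,
                      mentions$end)
  expect_equal(unname(extracted), mentions$text)
})

test_that("behavior profile controls the written recommendation", {
  always <- dplyr::mutate(default_behavior(), p_correct = 1, p_omit = 0,
                          p_wrong = 0)
  corp <- generate_corpus(60, seed = 5, behavior = always)
  pres <- corp$gold[corp$gold$gold_level != "NOT_APPLICABLE", ]
  expect_equal(pres$written_level, pres$gold_level)
  # the impression text carries the surface form of the gold level
  lv <- recommendation_levels()
  for (i in seq_len(5)) {
    id <- pres$report_id[i]
    imp <- corp$reports$impression[corp$reports$report_id == id]
    want <- lv$text[lv$level == pres$gold_level[i]]
    key <- paste(tolower(tokenize_text(want)$token), collapse = " ")
    expect_match(paste(tolower(tokenize_text(imp)$token), collapse = " "),
                 key, fixed = TRUE)
  }
  # nodule-free reports carry no present-nodule mention and no level
  na <- corp$gold[corp$gold$gold_level == "NOT_APPLICABLE", ]
  expect_true(all(is.na(na$written_level)))
  mentions <- gold_mentions(corp)
  vocab <- default_vocabulary()
  for (id in na$report_id) {
    m <- mentions[mentions$report_id == id & mentions$type == "NODULE_NAME", ]
    canon <- suppressWarnings(normalize_mentions(m, vocab)$canonical)
    expect_true(all(canon == "ABSENT"))
  }
})

test_that("injected omission/error rates are recovered empirically", {
  beh <- dplyr::mutate(default_behavior(), p_correct = 0.7,
                       p_omit = 0.2, p_wrong = 0.1)
  corp <- generate_corpus(1500, seed = 31, behavior = beh)
  pres <- corp$gold[corp$gold$gold_level != "NOT_APPLICABLE", ]
  n <- nrow(pres)
  correct <- sum(!is.na(pres$written_level) &
                   pres$written_level == pres$gold_level) / n
  omit <- mean(is.na(pres$written_level))
  wrong <- 1 - correct - omit
  expect_lt(abs(correct - 0.7), 3 * sqrt(0.7 * 0.3 / n))
  expect_lt(abs(omit - 0.2), 3 * sqrt(0.2 * 0.8 / n))
  expect_lt(abs(wrong - 0.1), 3 * sqrt(0.1 * 0.9 / n))
})

test_that("a missing vocabulary entry is reported by name", {
  vocab <- default_vocabulary()
  vocab <- vocab[!(vocab$type == "SOLIDITY" &
                     vocab$canonical == "GROUND_GLASS"), ]
  st <- tibble::tibble(present = TRUE, solidity = "GROUND_GLASS",
                       size_mm = 7, size_bin = "GE6", quantity = "SINGLE",
                       risk = "LOW")
  expect_error(render_report(st, vocab = vocab, seed = 1), "GROUND_GLASS")
})
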