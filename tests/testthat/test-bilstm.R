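# The compiled encoder+CRF is checked against (i) central finite
# differences of its own loss and (ii) the pure-R CRF primitives run on
# its emitted scores.

test_that("analytic gradients match finite differences", {
  withr::local_seed(7)
  tagset <- c("O", "B-A", "I-A", "B-B", "I-B")
  hp <- ner_hyperparams(embedding_dim = 3, hidden_dim = 4)
  params <- noduleaudit:::init_params(hp, n_vocab = 6, n_tags = 5, seed = 3)
  allowed <- is.finite(bio_transition_mask(tagset)) * 1
  seq <- c(0L, 2L, 5L, 1L, 3L)
  tags <- c(0L, 1L, 2L, 0L, 3L)
  res <- noduleaudit:::cpp_crf_nll_grad(params, seq, tags, allowed)
  expect_gt(res$nll, 0)
  eps <- 1e-6
  for (nm in names(res$grads)) {
    g <- res$grads[[nm]]
    idx <- sample(length(g), min(8, length(g)))
    for (i in idx) {
      p2 <- params
      p2[[nm]][i] <- p2[[nm]][i] + eps
      up <- noduleaudit:::cpp_crf_nll(p2, seq, tags, allowed)
      p2[[nm]][i] <- p2[[nm]][i] - 2 * eps
      dn <- noduleaudit:::cpp_crf_nll(p2, seq, tags, allowed)
      numeric_grad <- (up - dn) / (2 * eps)
      expect_equal(g[i], numeric_grad, tolerance = 1e-4)
    }
  }
})

test_that("compiled decoding equals the reference Viterbi on its emissions", {
  withr::local_seed(17)
  tagset <- nodule_tagset()
  mask <- bio_transition_mask(tagset)
  allowed <- is.finite(mask) * 1
  hp <- ner_hyperparams(embedding_dim = 4, hidden_dim = 5)
  for (rep in 1:5) {
    params <- noduleaudit:::init_params(hp, n_vocab = 10,
                                        n_tags = length(tagset),
                                        seed = rep)
    params$Tr <- params$Tr + matrix(rnorm(length(params$Tr), sd = 0.5),
                                    nrow(params$Tr))
    s <- sample(0:9, sample(2:8, 1), replace = TRUE)
    em <- noduleaudit:::cpp_crf_emissions(params, s)
    tr <- params$Tr + mask
    path_r <- viterbi_decode(em, tr)
    path_c <- noduleaudit:::cpp_crf_decode(params, list(s), allowed)[[1]] + 1
    expect_equal(as.integer(path_c), as.integer(path_r))
  }
})

test_that("training reduces the loss and is reproducible", {
  corp <- tiny_corpus()
  ann <- corp$annotations
  hp <- ner_hyperparams(max_epochs = 5, patience = 5)
  m1 <- ner_train(ann[1:40, ], ann[41:60, ], hyperparams = hp, seed = 9)
  expect_lt(dplyr::last(m1$history$train_nll), m1$history$train_nll[1])
  m2 <- ner_train(ann[1:40, ], ann[41:60, ], hyperparams = hp, seed = 9)
  expect_identical(m1$history, m2$history)
  expect_identical(m1$params, m2$params)
})

test_that("a trained model recovers gold spans on in-vocabulary text", {
  corp <- tiny_corpus()
  ann <- corp$annotations
  hp <- ner_hyperparams(max_epochs = 20, patience = 20)
  model <- ner_train(ann, ann, hyperparams = hp, seed = 4)
  expect_gte(model$val_f1, 0.99) # memorizes its templated training set
  pred <- predict(model, corp$reports[1:5, ])
  gold <- gold_mentions(corp)
  for (id in corp$reports$report_id[1:5]) {
    g <- gold[gold$report_id == id, ]
    # gold mentions cover findings + impression; compare findings spans only
    n_find <- nchar(corp$reports$findings[corp$reports$report_id == id])
    g <- g[g$end <= n_find, ]
    p <- pred[pred$report_id == id, ]
    expect_setequal(paste(p$type, p$start, p$end), paste(g$type, g$start, g$end))
  }
})

test_that("prediction handles empty and out-of-vocabulary text", {
  corp <- tiny_corpus()
  hp <- ner_hyperparams(max_epochs = 1, patience = 1)
  model <- ner_train(corp$annotations[1:10, ], hyperparams = hp, seed = 2)
  expect_equal(nrow(predict(model, c(r1 = ""))), 0)
  oov <- predict(model, c(r2 = "zzz qqq xxyy aleatory"))
  expect_true(all(oov$type %in% entity_types()))
  expect_true(all(oov$start >= 0 & oov$end <= nchar("zzz qqq xxyy aleatory")))
})
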