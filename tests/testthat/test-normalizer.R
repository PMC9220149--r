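test_that("the default catalog has the canonical per-type composition", {
  counts <- dplyr::count(default_vocabulary(), type)
  want <- c(FOLLOWUP = 9, LOCATION = 37, NODULE_NAME = 13, QUANTITY = 6,
            RISK_LEVEL = 14, SHAPE = 11, SOLIDITY = 7)
  expect_equal(stats::setNames(counts$n, counts$type), want)
  expect_equal(sum(counts$n), 97)
})

test_that("normalization is idempotent, total and maps unknowns to UNKNOWN", {
  expect_equal(normalize_mention("ground-glass", "SOLIDITY"), "GROUND_GLASS")
  expect_equal(normalize_mention("GROUND_GLASS", "SOLIDITY"), "GROUND_GLASS")
  expect_warning(
    out <- normalize_mention("frosted glass", "SOLIDITY"),
    "UNKNOWN")
  expect_equal(out, "UNKNOWN")
  # total over the whole default catalog
  vocab <- default_vocabulary()
  got <- normalize_mentions(tibble::tibble(type = vocab$type,
                                           text = vocab$surface))
  expect_equal(got$canonical, vocab$canonical)
})

test_that("sizes parse to millimetres with cm conversion and axis means", {
  expect_equal(parse_size_mm("6mm"), 6)
  expect_equal(parse_size_mm("7 mm"), 7)
  expect_equal(parse_size_mm("0.8cm"), 8)
  expect_equal(parse_size_mm("0.60 cm"), 6)
  expect_equal(parse_size_mm("10×8mm"), 9)
  expect_equal(parse_size_mm("10 x 8 mm"), 9)
  expect_error(parse_size_mm("large"), "large")
})

test_that("size bins follow the solidity-dependent boundaries", {
  expect_equal(assign_size_bin(c(5.9, 6, 8, 8.1), "SOLID"),
               c("LT6", "SIX_TO_8", "SIX_TO_8", "GT8"))
  expect_equal(assign_size_bin(6, "GROUND_GLASS"), "GE6")
  expect_equal(assign_size_bin(9, "PART_SOLID"), "GE6")
  expect_equal(assign_size_bin(5.9, "PART_SOLID"), "LT6")
  expect_error(assign_size_bin(0, "SOLID"), "positive")
  expect_error(assign_size_bin(5, "SEMI"), "solidity")
})

test_that("slot assembly fills, defaults and escalates as specified", {
  m <- tibble::tibble(
    type = c("NODULE_NAME", "SOLIDITY", "SIZE", "QUANTITY", "RISK_LEVEL"),
    text = c("pulmonary nodule", "solid", "7 mm", "single", "low risk"))
  st <- assemble_state(m)
  expect_equal(st, tibble::tibble(present = TRUE, solidity = "SOLID",
                                  size_mm = 7, size_bin = "SIX_TO_8",
                                  quantity = "SINGLE", risk = "LOW"))
  # no mentions, or absence mentions only -> absent state
  expect_false(assemble_state(m[0, ])$present)
  expect_false(
    assemble_state(tibble::tibble(type = "NODULE_NAME",
                                  text = "no pulmonary nodules"))$present)
  # two sizes: the largest ("most suspicious") wins
  m2 <- dplyr::bind_rows(m, tibble::tibble(type = "SIZE", text = "9 mm"))
  st2 <- assemble_state(m2)
  expect_equal(st2$size_mm, 9)
  expect_equal(st2$size_bin, "GT8")
  # MULTIPLE and HIGH dominate within their slots
  m3 <- dplyr::bind_rows(m, tibble::tibble(
    type = c("QUANTITY", "RISK_LEVEL"), text = c("multiple", "high risk")))
  st3 <- assemble_state(m3)
  expect_equal(st3$quantity, "MULTIPLE")
  expect_equal(st3$risk, "HIGH")
  # missing slots default to the least-escalating branch, with warnings
  m4 <- tibble::tibble(type = "NODULE_NAME", text = "lung nodule")
  w <- testthat::capture_warnings(st4 <- assemble_state(m4))
  expect_true(any(grepl("default", w)))
  expect_equal(st4[, c("solidity", "size_bin", "quantity", "risk")],
               tibble::tibble(solidity = "SOLID", size_bin = "LT6",
                              quantity = "SINGLE", risk = "LOW"))
  # conflicting solidity keeps the first mention and warns
  m5 <- dplyr::bind_rows(m, tibble::tibble(type = "SOLIDITY",
                                           text = "ground-glass"))
  expect_warning(st5 <- assemble_state(m5), "conflicting solidity")
  expect_equal(st5$solidity, "SOLID")
})

test_that("assembly is permutation-invariant apart from the logged rule", {
  withr::local_seed(3)
  m <- tibble::tibble(
    type = c("NODULE_NAME", "SOLIDITY", "SIZE", "SIZE", "QUANTITY",
             "RISK_LEVEL", "LOCATION"),
    text = c("lung nodule", "part-solid", "4 mm", "9 mm", "several",
             "heavy smoker", "left apex"))
  base <- assemble_state(m)
  for (i in 1:5) {
    expect_equal(assemble_state(m[sample(nrow(m)), ]), base)
  }
})

test_that("gold mentions reassemble exactly the sampled state", {
  corp <- generate_corpus(120, seed = 55)
  mentions <- gold_mentions(corp)
  states <- suppressWarnings(fill_slots(mentions))
  gold <- corp$gold[match(states$report_id, corp$gold$report_id), ]
  expect_equal(states$present, gold$present)
  pres <- states$present
  expect_equal(states$solidity[pres], gold$solidity[pres])
  expect_equal(states$size_mm[pres], gold$size_mm[pres])
  expect_equal(states$size_bin[pres], gold$size_bin[pres])
  expect_equal(states$quantity[pres], gold$quantity[pres])
  expect_equal(states$risk[pres], gold$risk[pres])
})

test_that("catalog YAML round-trips", {
  vocab <- default_vocabulary()
  tmp <- withr::local_tempfile(fileext = ".yaml")
  write_vocabulary(vocab, tmp)
  back <- read_vocabulary(tmp)
  expect_equal(dplyr::arrange(back, type, surface),
               dplyr::arrange(vocab, type, surface))
})
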