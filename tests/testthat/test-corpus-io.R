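test_that("JSONL report corpus round-trips losslessly and in order", {
  corp <- tiny_corpus()
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  write_reports(corp$reports, tmp)
  back <- read_reports(tmp)
  expect_equal(back$report_id, corp$reports$report_id)
  expect_equal(back$findings, corp$reports$findings)
  expect_equal(back$impression, corp$reports$impression)

  # empty corpus -> empty file -> empty tibble
  empty <- corp$reports[0, ]
  write_reports(empty, tmp)
  expect_equal(nrow(read_reports(tmp)), 0)
})

test_that("malformed corpus lines are rejected with their line number", {
  tmp <- withr::local_tempfile(fileext = ".jsonl")
  ok <- '{"report_id":"A","findings":"x","impression":"y"}'
  writeLines(c(ok, '{"report_id":"B","impression":"y"}'), tmp)
  expect_error(read_reports(tmp), "line 2.*findings")
  writeLines(c(ok, "{not json"), tmp)
  expect_error(read_reports(tmp), "line 2")
  writeLines(c(ok, ok), tmp)
  expect_error(read_reports(tmp), "duplicate report_id")
  expect_error(
    write_reports(tibble::tibble(report_id = c("A", "A"), findings = "x",
                                 impression = "y"), tmp),
    "duplicate")
})

test_that("BIO TSV round-trips and rejects invalid sequences", {
  corp <- tiny_corpus()
  ann <- corp$annotations[1:10, ]
  tmp <- withr::local_tempfile(fileext = ".tsv")
  write_bio(ann, tmp)
  back <- read_bio(tmp)
  expect_equal(back$report_id, ann$report_id)
  expect_equal(back$tokens, ann$tokens)
  expect_equal(back$tags, ann$tags)

  # all-O sequences are valid
  writeLines("a\tO\nb\tO", tmp)
  expect_equal(read_bio(tmp)$tags[[1]], c("O", "O"))

  # I- after O violates BIO; the error names the sequence
  writeLines(c("a\tO\nb\tO", "", "a\tO\nb\tI-SIZE"), tmp)
  expect_error(read_bio(tmp), "sequence 2.*I-SIZE")

  # ragged line
  writeLines("a\tO\tX", tmp)
  expect_error(read_bio(tmp), "2 tab-separated")

  expect_error(
    write_bio(tibble::tibble(report_id = "r", tokens = list(c("a", "b")),
                             tags = list(c("O", "I-SIZE"))), tmp),
    "invalid BIO")
})

test_that("split_corpus honours ratios per stratum and is reproducible", {
  reports <- tibble::tibble(report_id = as.character(1:48), findings = "x",
                            impression = "")
  s1 <- split_corpus(reports, c(0.5, 0.25, 0.25), seed = 7)
  expect_equal(as.vector(table(s1$subset)[c("train", "validation", "test")]),
               c(24L, 12L, 12L))
  s2 <- split_corpus(reports, c(0.5, 0.25, 0.25), seed = 7)
  expect_identical(s1, s2)

  # two strata of 24 -> each split 12/6/6
  reports$grp <- rep(c("a", "b"), each = 24)
  s3 <- split_corpus(reports, seed = 3, strata = "grp")
  tab <- table(reports$grp[match(s3$report_id, reports$report_id)], s3$subset)
  expect_true(all(tab[, "train"] == 12 & tab[, "validation"] == 6 &
                    tab[, "test"] == 6))

  # a tiny stratum goes wholly to train, with a warning
  reports$grp[1:3] <- "c"
  expect_warning(s4 <- split_corpus(reports, seed = 3, strata = "grp"),
                 "wholly to train")
  expect_true(all(s4$subset[s4$report_id %in% as.character(1:3)] == "train"))
})

test_that("splits partition the corpus for arbitrary sizes and seeds", {
  for (n in c(5, 17, 100)) {
    reports <- tibble::tibble(report_id = sprintf("r%03d", 1:n),
                              findings = "x", impression = "")
    s <- split_corpus(reports, seed = n)
    expect_setequal(s$report_id, reports$report_id)
    expect_false(anyNA(s$subset))
    sizes <- table(s$subset)
    expect_true(all(abs(sizes - n * c(0.5, 0.25, 0.25)) <= 1))
  }
})

test_that("split manifests round-trip through JSON", {
  reports <- tibble::tibble(report_id = as.character(1:20), findings = "x",
                            impression = "")
  s <- split_corpus(reports, seed = 2)
  tmp <- withr::local_tempfile(fileext = ".json")
  write_split_manifest(s, tmp)
  back <- read_split_manifest(tmp)
  expect_setequal(back$report_id[back$subset == "train"],
                  s$report_id[s$subset == "train"])
  expect_setequal(back$report_id[back$subset == "test"],
                  s$report_id[s$subset == "test"])
})
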