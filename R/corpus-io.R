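#' Read and write report corpora (JSONL)
#'
#' A corpus is stored as JSON Lines: one object per report with keys
#' `report_id`, `findings`, `impression` and optionally `meta` (a flat
#' string map). `read_reports()` preserves file order and validates each
#' line; `write_reports()` is its lossless inverse.
#'
#' @param path file path.
#' @param reports tibble with columns `report_id`, `findings`, `impression`
#'   and optionally a list-column `meta` of named character vectors.
#' @return `read_reports()`: tibble with columns `report_id`, `findings`,
#'   `impression`, `meta` (list-column). `write_reports()`: `path`,
#'   invisibly.
#' @export
#' @examples
#' tmp <- tempfile(fileext = ".jsonl")
#' r <- tibble::tibble(report_id = "R1", findings = "a nodule",
#'                     impression = "benign", meta = list(c(age = "60")))
#' write_reports(r, tmp)
#' read_reports(tmp)
read_reports <- function(path) {
  if (!file.exists(path)) stop_bad_arg("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(tibble::tibble(report_id = character(), findings = character(),
                          impression = character(), meta = list()))
  }
  parse_line <- function(i) {
    rec <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = TRUE),
                    error = function(e) {
                      stop_bad_arg("malformed JSON on line %d: %s", i,
                                   conditionMessage(e))
                    })
    for (key in c("report_id", "findings", "impression")) {
      if (is.null(rec[[key]])) {
        stop_bad_arg("line %d is missing required key \"%s\"", i, key)
      }
    }
    if (!nzchar(rec$findings)) stop_bad_arg("line %d has empty findings", i)
    meta <- rec$meta %||% list()
    tibble::tibble(report_id = as.character(rec$report_id),
                   findings = as.character(rec$findings),
                   impression = as.character(rec$impression),
                   meta = list(unlist(meta) %||% character()))
  }
  out <- dplyr::bind_rows(purrr::map(seq_along(lines), parse_line))
  dup <- out$report_id[duplicated(out$report_id)]
  if (length(dup) > 0) {
    stop_bad_arg("duplicate report_id(s): %s",
                 paste(unique(dup), collapse = ", "))
  }
  out
}

#' @rdname read_reports
#' @export
write_reports <- function(reports, path) {
  assert_columns(reports, c("report_id", "findings", "impression"))
  dup <- reports$report_id[duplicated(reports$report_id)]
  if (length(dup) > 0) {
    stop_bad_arg("duplicate report_id(s): %s",
                 paste(unique(dup), collapse = ", "))
  }
  lines <- purrr::map_chr(seq_len(nrow(reports)), function(i) {
    meta <- if ("meta" %in% names(reports)) reports$meta[[i]] else character()
    obj <- list(report_id = reports$report_id[i],
                findings = reports$findings[i],
                impression = reports$impression[i],
                meta = as.list(meta))
    jsonlite::toJSON(obj, auto_unbox = TRUE)
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Read and write BIO-annotated token files (CoNLL-style TSV)
#'
#' Two tab-separated columns (`token`, `tag`), a blank line between
#' sequences, and a `# id = <report_id>` comment line opening each
#' sequence. Tags must form valid BIO sequences over [nodule_tagset()]
#' (an `I-X` may only continue a `B-X`/`I-X` of the same type).
#'
#' @param path file path.
#' @param annotations tibble with columns `report_id`, `tokens`
#'   (list-column of character vectors) and `tags` (list-column, same
#'   lengths).
#' @param tagset valid tags; default [nodule_tagset()].
#' @return `read_bio()`: annotations tibble as above; `write_bio()`:
#'   `path`, invisibly.
#' @export
read_bio <- function(path, tagset = nodule_tagset()) {
  if (!file.exists(path)) stop_bad_arg("no such file: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  blank <- !nzchar(trimws(lines))
  seq_id <- cumsum(c(TRUE, blank[-length(lines)])) # sequence index per line
  keep <- !blank
  chunks <- split(lines[keep], seq_id[keep])
  parse_chunk <- function(chunk, idx) {
    id_line <- grepl("^# id = ", chunk)
    rid <- if (any(id_line)) sub("^# id = ", "", chunk[id_line][1]) else
      sprintf("seq%03d", idx)
    body <- chunk[!grepl("^#", chunk)]
    parts <- strsplit(body, "\t", fixed = TRUE)
    ragged <- lengths(parts) != 2
    if (any(ragged)) {
      stop_bad_arg("sequence %d: line \"%s\" does not have 2 tab-separated columns",
                   idx, body[ragged][1])
    }
    tokens <- purrr::map_chr(parts, 1)
    tags <- purrr::map_chr(parts, 2)
    viol <- bio_violation(tags, tagset)
    if (!is.null(viol)) stop_bad_arg("sequence %d: %s", idx, viol)
    tibble::tibble(report_id = rid, tokens = list(tokens), tags = list(tags))
  }
  if (length(chunks) == 0) {
    return(tibble::tibble(report_id = character(), tokens = list(),
                          tags = list()))
  }
  dplyr::bind_rows(purrr::imap(unname(chunks),
                               function(ch, i) parse_chunk(ch, as.integer(i))))
}

#' @rdname read_bio
#' @export
write_bio <- function(annotations, path, tagset = nodule_tagset()) {
  assert_columns(annotations, c("report_id", "tokens", "tags"))
  blocks <- purrr::map_chr(seq_len(nrow(annotations)), function(i) {
    tokens <- annotations$tokens[[i]]
    tags <- annotations$tags[[i]]
    if (length(tokens) != length(tags)) {
      stop_bad_arg("sequence %d: %d tokens but %d tags", i,
                   length(tokens), length(tags))
    }
    viol <- bio_violation(tags, tagset)
    if (!is.null(viol)) stop_bad_arg("sequence %d: %s", i, viol)
    paste(c(sprintf("# id = %s", annotations$report_id[i]),
            paste(tokens, tags, sep = "\t")), collapse = "\n")
  })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(paste(blocks, collapse = "\n\n"), con, useBytes = TRUE)
  invisible(path)
}

#' Stratified train/validation/test split
#'
#' Randomly partitions a corpus into train/validation/test subsets at the
#' given ratios, independently within each stratum, so every stratum's
#' proportions are honoured to within one report (largest-remainder
#' allocation). Strata with fewer than 4 reports are assigned wholly to the
#' training set with a warning.
#'
#' @param reports reports tibble (see [read_reports()]).
#' @param ratios numeric length-3 vector summing to 1
#'   (train, validation, test).
#' @param seed integer seed making the split reproducible.
#' @param strata `NULL` (single stratum), a column name in `reports`, or a
#'   function mapping the reports tibble to a vector of stratum labels.
#' @return tibble with columns `report_id` and `subset`
#'   (factor train/validation/test).
#' @export
#' @examples
#' r <- tibble::tibble(report_id = as.character(1:48), findings = "x",
#'                     impression = "")
#' table(split_corpus(r, seed = 7)$subset)
split_corpus <- function(reports, ratios = c(0.5, 0.25, 0.25), seed,
                         strata = NULL) {
  assert_columns(reports, "report_id")
  if (nrow(reports) == 0) stop_bad_arg("corpus is empty")
  if (length(ratios) != 3 || abs(sum(ratios) - 1) > 1e-8) {
    stop_bad_arg("ratios must be 3 proportions summing to 1")
  }
  labels <- if (is.null(strata)) {
    rep("all", nrow(reports))
  } else if (is.function(strata)) {
    as.character(strata(reports))
  } else {
    as.character(reports[[strata]])
  }
  subsets <- c("train", "validation", "test")
  with_seed_or_not(seed, {
    pieces <- purrr::map(split(reports$report_id, labels), function(ids) {
      n <- length(ids)
      if (n < 4) {
        warn(sprintf("stratum with %d report(s) assigned wholly to train", n),
             class = "noduleaudit_small_stratum")
        return(tibble::tibble(report_id = ids, subset = "train"))
      }
      sizes <- floor(n * ratios)
      rem <- n - sum(sizes)
      if (rem > 0) {
        frac <- n * ratios - sizes
        sizes[order(-frac)[seq_len(rem)]] <-
          sizes[order(-frac)[seq_len(rem)]] + 1
      }
      shuffled <- sample(ids, n)
      tibble::tibble(report_id = shuffled,
                     subset = rep(subsets, times = sizes))
    })
    out <- dplyr::bind_rows(pieces)
    out <- out[match(reports$report_id, out$report_id), ]
    out$subset <- factor(out$subset, levels = subsets)
    out
  })
}

#' Write / read a split manifest (JSON with three report-id arrays)
#'
#' @param split tibble from [split_corpus()].
#' @param path file path.
#' @return `write_split_manifest()`: `path` invisibly;
#'   `read_split_manifest()`: split tibble.
#' @export
write_split_manifest <- function(split, path) {
  obj <- purrr::map(split(split$report_id, split$subset), as.character)
  jsonlite::write_json(obj, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split_manifest
#' @export
read_split_manifest <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  dplyr::bind_rows(purrr::imap(obj[c("train", "validation", "test")],
                               ~ tibble::tibble(report_id = .x, subset = .y))) |>
    dplyr::mutate(subset = factor(.data$subset,
                                  levels = c("train", "validation", "test")))
}
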