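#' Extract the follow-up level written in an impression
#'
#' Runs the extraction model over each impression, normalizes `FOLLOWUP`
#' mentions to recommendation levels, and returns the written level per
#' report: `NA` when no follow-up phrase is present, and — when several
#' conflicting levels are written — the most escalated one (highest level
#' rank), with a warning.
#'
#' @param reports reports tibble with `report_id` and `impression`.
#' @param model extraction model (`ner_model` or `dictionary_tagger`).
#' @param catalog catalog tibble.
#' @return tibble with columns `report_id`, `written_level`.
#' @export
extract_written_level <- function(reports, model,
                                  catalog = default_vocabulary()) {
  assert_columns(reports, c("report_id", "impression"))
  mentions <- stats::predict(model, reports, text = "impression")
  fu <- dplyr::filter(mentions, .data$type == "FOLLOWUP")
  lv <- recommendation_levels()
  if (nrow(fu) > 0) {
    fu <- normalize_mentions(fu, catalog)
    fu <- dplyr::filter(fu, .data$canonical %in% lv$level)
    fu$rank <- lv$rank[match(fu$canonical, lv$level)]
    conflicts <- fu |>
      dplyr::distinct(.data$report_id, .data$canonical) |>
      dplyr::count(.data$report_id) |>
      dplyr::filter(.data$n > 1)
    if (nrow(conflicts) > 0) {
      warn(sprintf("%d report(s) with conflicting written levels; keeping the most escalated",
                   nrow(conflicts)),
           class = "noduleaudit_escalation")
    }
    fu <- fu |>
      dplyr::group_by(.data$report_id) |>
      dplyr::slice_max(.data$rank, n = 1, with_ties = FALSE) |>
      dplyr::ungroup() |>
      dplyr::select("report_id", written_level = "canonical")
  } else {
    fu <- tibble::tibble(report_id = character(),
                         written_level = character())
  }
  dplyr::left_join(tibble::tibble(report_id = reports$report_id), fu,
                   by = "report_id")
}

#' Audit written against generated recommendations
#'
#' A report matches when the level written in its impression equals the
#' system-generated level (same canonical level, i.e. same follow-up
#' frequency and method). A missing written recommendation is a mismatch
#' at every level L1-L9 — including "no routine follow up required", which
#' must still be stated — but counts as a match for `NOT_APPLICABLE`
#' (nodule-free) reports, where writing nothing is correct.
#'
#' @param generated tibble with `report_id` and `level` (e.g. from
#'   [recommend()]), or a named character vector of levels.
#' @param written tibble with `report_id` and `written_level` (e.g. from
#'   [extract_written_level()]).
#' @return verdicts tibble: `report_id`, `generated`, `written`, `match`.
#' @export
audit_reports <- function(generated, written) {
  gen <- if (is.character(generated)) {
    tibble::tibble(report_id = names(generated) %||%
                     as.character(seq_along(generated)),
                   generated = unname(generated))
  } else {
    assert_columns(generated, c("report_id", "level"))
    tibble::tibble(report_id = generated$report_id,
                   generated = generated$level)
  }
  valid <- c(recommendation_levels()$level, "NOT_APPLICABLE")
  bad <- setdiff(unique(gen$generated), valid)
  if (length(bad) > 0) {
    stop_bad_arg("generated level(s) outside L1..L9/NOT_APPLICABLE: %s",
                 paste(bad, collapse = ", "))
  }
  assert_columns(written, c("report_id", "written_level"))
  out <- dplyr::left_join(gen, written, by = "report_id") |>
    dplyr::rename(written = "written_level")
  dplyr::mutate(out, match = dplyr::if_else(
    is.na(.data$written),
    .data$generated == "NOT_APPLICABLE",
    .data$written == .data$generated))
}

#' Per-level and overall matching rates
#'
#' Groups verdicts by generated level and computes report counts and
#' matching rates per level (the nine levels in canonical order, plus a
#' `NOT_APPLICABLE` row when present) and overall. The overall rate is the
#' count-weighted mean of the per-level rates.
#'
#' @param verdicts verdicts tibble from [audit_reports()].
#' @return tibble of class `audit_table`: `level`, `level_label`,
#'   `n_reports`, `n_matched`, `matching_rate`; the overall rate is the
#'   `"overall"` attribute and is also returned by [glance()].
#' @export
audit_corpus <- function(verdicts) {
  assert_columns(verdicts, c("generated", "match"))
  if (nrow(verdicts) == 0) stop_bad_arg("no verdicts to audit")
  lv <- recommendation_levels()
  levels_present <- c(lv$level,
                      if ("NOT_APPLICABLE" %in% verdicts$generated)
                        "NOT_APPLICABLE")
  per <- verdicts |>
    dplyr::mutate(generated = factor(.data$generated,
                                     levels = levels_present)) |>
    dplyr::group_by(.data$generated, .drop = FALSE) |>
    dplyr::summarise(n_reports = dplyr::n(),
                     n_matched = sum(.data$match), .groups = "drop") |>
    dplyr::mutate(level = as.character(.data$generated),
                  level_label = recommendation_text(.data$level),
                  matching_rate = ifelse(.data$n_reports > 0,
                                         .data$n_matched / .data$n_reports,
                                         NA_real_)) |>
    dplyr::select("level", "level_label", "n_reports", "n_matched",
                  "matching_rate")
  out <- structure(per, class = c("audit_table", class(per)),
                   overall = sum(per$n_matched) / sum(per$n_reports))
  out
}

#' @export
glance.audit_table <- function(x, ...) {
  tibble::tibble(n_reports = sum(x$n_reports),
                 n_matched = sum(x$n_matched),
                 matching_rate = attr(x, "overall"))
}

#' @export
print.audit_table <- function(x, ...) {
  cat("<audit_table>\n")
  NextMethod()
  cat(sprintf("overall matching rate: %.2f%% (%d / %d)\n",
              100 * attr(x, "overall"), sum(x$n_matched), sum(x$n_reports)))
  invisible(x)
}

#' Write an audit table to CSV
#'
#' Emits `level_label`, `n_reports`, `matching_rate` rows in canonical
#' level order, followed by a `Total` row.
#'
#' @param audit an `audit_table`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_audit_table <- function(audit, path) {
  df <- data.frame(level_label = c(audit$level_label, "Total"),
                   n_reports = c(audit$n_reports, sum(audit$n_reports)),
                   matching_rate = c(audit$matching_rate,
                                     attr(audit, "overall")))
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}
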