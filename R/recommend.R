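#' Generate follow-up recommendations
#'
#' The end-to-end recommendation stage: entity mentions are normalized and
#' filled into the five query slots ([fill_slots()]), and each resulting
#' state selects its unique chain in the guideline graph
#' ([query_recommendation()]). Reports without a present-nodule mention
#' receive `NOT_APPLICABLE`. The function is total over valid mentions:
#' it never throws on a validated graph.
#'
#' When `mentions` is omitted, `reports` and `model` must be given and the
#' mentions are first extracted from the findings text with the model.
#'
#' @param graph a validated `guideline_graph`.
#' @param mentions mentions tibble with `report_id`, `type`, `text`.
#' @param reports reports tibble (used when `mentions` is `NULL`).
#' @param model extraction model (`ner_model` or `dictionary_tagger`).
#' @param catalog catalog tibble; defaults to the graph's.
#' @return tibble with one row per report: slot columns plus `level`,
#'   `text`, `rule_id`. Attribute `"seconds_per_report"` records the mean
#'   per-report processing time.
#' @export
#' @examples
#' g <- build_guideline_graph()
#' m <- tibble::tibble(report_id = "R1",
#'   type = c("NODULE_NAME", "SOLIDITY", "SIZE"),
#'   text = c("pulmonary nodule", "ground-glass", "7 mm"))
#' suppressWarnings(recommend(g, m))
recommend <- function(graph, mentions = NULL, reports = NULL, model = NULL,
                      catalog = NULL) {
  stopifnot(inherits(graph, "guideline_graph"))
  catalog <- catalog %||% graph$catalog
  t0 <- proc.time()[["elapsed"]]
  if (is.null(mentions)) {
    if (is.null(reports) || is.null(model)) {
      stop_bad_arg("supply either `mentions` or both `reports` and `model`")
    }
    mentions <- stats::predict(model, reports)
  }
  ids <- unique(c(mentions$report_id, reports$report_id))
  states <- fill_slots(mentions, catalog = catalog)
  missing <- setdiff(ids, states$report_id)
  if (length(missing) > 0) {
    states <- dplyr::bind_rows(
      states,
      dplyr::bind_cols(tibble::tibble(report_id = missing), empty_state()))
  }
  states <- states[match(ids, states$report_id), ]
  recs <- purrr::map(seq_len(nrow(states)),
                     ~ query_recommendation(graph, states[.x, ]))
  out <- dplyr::bind_cols(states, dplyr::bind_rows(recs))
  attr(out, "seconds_per_report") <-
    (proc.time()[["elapsed"]] - t0) / max(1, nrow(out))
  out
}
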