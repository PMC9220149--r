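#' Plot NER evaluation metrics
#'
#' Per-entity-type bars of precision, recall and F1 (the micro-averaged
#' `Total` row is drawn last).
#'
#' @param object a `ner_metrics` tibble from [evaluate_ner()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ner_metrics <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[c("entity_type", "precision", "recall", "f1")],
    -"entity_type", names_to = "metric", values_to = "value")
  df$entity_type <- factor(df$entity_type,
                           levels = c(entity_types(), "Total"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$entity_type, y = .data$value,
                                   fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = NULL,
                  title = "Entity extraction performance") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot an audit table
#'
#' Per-level matching rates with report counts, and the overall rate as a
#' dashed reference line.
#'
#' @param object an `audit_table` from [audit_corpus()].
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.audit_table <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$level <- factor(df$level, levels = df$level)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$level,
                                   y = .data$matching_rate)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = attr(object, "overall"),
                        linetype = "dashed") +
    ggplot2::geom_text(ggplot2::aes(label = .data$n_reports), vjust = -0.4,
                       size = 3) +
    ggplot2::scale_y_continuous(limits = c(0, 1.05)) +
    ggplot2::labs(x = "generated recommendation level", y = "matching rate",
                  title = "Follow-up recommendation audit") +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' Training negative log-likelihood and validation entity F1 by epoch.
#'
#' @param object a `ner_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.ner_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history, -"epoch",
                            names_to = "series", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(title = "BiLSTM+CRF training history") +
    ggplot2::theme_minimal()
}
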