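#' Default impression-writing behavior profile
#'
#' Per-recommendation-level probabilities that a report's impression states
#' the correct follow-up recommendation (`p_correct`), omits it (`p_omit`)
#' or states a different level's recommendation (`p_wrong`);
#' `p_correct + p_omit + p_wrong = 1` per level. The default `p_correct`
#' values are the per-level matching rates observed in the hospital audit
#' this generator emulates, with the residual mass split 80/20 between
#' omission and error — omission dominates because doctors tend to skip
#' spelling out the recommendation where none is required. The
#' `NOT_APPLICABLE` row governs nodule-free reports, where the correct
#' behavior is to write no recommendation.
#'
#' @return tibble with columns `level`, `p_correct`, `p_omit`, `p_wrong`.
#' @export
default_behavior <- function() {
  rates <- c(L1 = 0.8946, L2 = 0.9502, L3 = 0.9838, L4 = 0.9851,
             L5 = 0.9897, L6 = 0.9987, L7 = 0.9917, L8 = 0.9877,
             L9 = 0.9825, NOT_APPLICABLE = 0.95)
  tibble::tibble(level = names(rates), p_correct = unname(rates),
                 p_omit = 0.8 * (1 - p_correct),
                 p_wrong = 1 - p_correct - p_omit)
}

#' Default nodule-state distribution
#'
#' Reports are predominantly benign: the level weights mirror the heavy
#' skew of the emulated audit (77% of reports at "no routine follow up"),
#' renormalized over the nine levels; a small fraction of reports
#' (`p_absent`) describes no nodule at all, exercising the not-applicable
#' path. Within a level the matching states are drawn uniformly and the
#' size uniformly within its bin.
#'
#' @return list with elements `p_absent` (scalar) and `levels` (tibble
#'   `level`, `weight`).
#' @export
default_state_weights <- function() {
  counts <- c(L1 = 37049, L2 = 4501, L3 = 1539, L4 = 769, L5 = 1539,
              L6 = 1731, L7 = 500, L8 = 269, L9 = 192)
  list(p_absent = 0.04,
       levels = tibble::tibble(level = names(counts),
                               weight = unname(counts) / sum(counts)))
}

sample_size_in_bin <- function(bin) {
  switch(bin,
         LT6 = round(runif(1, 2, 5.8), 1),
         SIX_TO_8 = round(runif(1, 6, 8), 1),
         GT8 = round(runif(1, 8.2, 25), 1),
         GE6 = round(runif(1, 6, 25), 1))
}

sample_states_impl <- function(n, weights) {
  states <- enumerate_states()
  states$level <- oracle_recommend(states)
  by_level <- split(states, states$level)
  draw_one <- function() {
    if (runif(1) < weights$p_absent) {
      s <- empty_state()
      s$gold_level <- "NOT_APPLICABLE"
      return(s)
    }
    lvl <- sample(weights$levels$level, 1, prob = weights$levels$weight)
    cand <- by_level[[lvl]]
    s <- cand[sample(nrow(cand), 1), ]
    s$size_mm <- sample_size_in_bin(s$size_bin)
    s$level <- NULL
    dplyr::mutate(s, size_mm = .data$size_mm, gold_level = lvl)
  }
  dplyr::bind_rows(purrr::map(seq_len(n), ~ draw_one()))
}

#' Sample nodule states
#'
#' Draws complete nodule states (or the nodule-free state) from a
#' configurable categorical distribution; see [default_state_weights()].
#' Deterministic given `seed`.
#'
#' @param n number of states.
#' @param weights state distribution (see [default_state_weights()]).
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return tibble of states with a `gold_level` column (the oracle
#'   recommendation).
#' @export
#' @examples
#' sample_states(3, seed = 1)
sample_states <- function(n, weights = default_state_weights(), seed = NULL) {
  stopifnot(n >= 1)
  with_seed_or_not(seed, sample_states_impl(n, weights))
}

surface_for <- function(vocab, type, canonical = NULL) {
  rows <- vocab[vocab$type == type, ]
  if (!is.null(canonical)) rows <- rows[rows$canonical == canonical, ]
  if (nrow(rows) == 0) {
    stop_bad_arg("vocabulary has no %s surface form for canonical value \"%s\"",
                 type, canonical %||% "(any)")
  }
  rows$surface[sample(nrow(rows), 1)]
}

entity_tokens <- function(surface, type) {
  toks <- tokenize_tokens(surface)
  list(tokens = toks,
       tags = c(paste0("B-", type), rep(paste0("I-", type),
                                        length(toks) - 1)))
}

plain <- function(text) {
  toks <- tokenize_tokens(text)
  list(tokens = toks, tags = rep("O", length(toks)))
}

cat_pieces <- function(...) {
  pieces <- list(...)
  list(tokens = unname(unlist(purrr::map(pieces, "tokens"))),
       tags = unname(unlist(purrr::map(pieces, "tags"))))
}

# size surface renderings; all parse back to exactly `mm` millimetres
render_size <- function(mm) {
  form <- sample(c("mm_space", "mm_tight", "cm", "axes"), 1)
  switch(form,
         mm_space = sprintf("%g mm", mm),
         mm_tight = sprintf("%gmm", mm),
         cm = sprintf("%.2f cm", mm / 10),
         axes = sprintf("%g×%g mm", mm + 0.5, mm - 0.5))
}

distractor_pool <- function() {
  # several sentences deliberately contain vocabulary surface forms in
  # non-entity roles ("multiple", "low risk", "solid", "ground glass
  # opacity") so that context-free dictionary matching produces false
  # positives the sequence model must learn to avoid
  c("the heart size is within normal limits .",
    "no pleural effusion is seen .",
    "multiple prior studies were reviewed for comparison .",
    "low risk of motion artifact in this study .",
    "the solid organs of the upper abdomen are unremarkable .",
    "the trachea is midline .",
    "degenerative changes are noted in the thoracic spine .",
    "no ground glass opacity in the remaining lung .")
}

render_findings <- function(state, vocab) {
  sentences <- list()
  if (isTRUE(state$present)) {
    qty <- entity_tokens(surface_for(vocab, "QUANTITY", state$quantity),
                         "QUANTITY")
    sol <- entity_tokens(surface_for(vocab, "SOLIDITY", state$solidity),
                         "SOLIDITY")
    nam <- entity_tokens(surface_for(vocab, "NODULE_NAME", "PRESENT"),
                         "NODULE_NAME")
    loc <- entity_tokens(surface_for(vocab, "LOCATION"), "LOCATION")
    sentences$nodule <- cat_pieces(plain("there is"), qty, sol, nam,
                                   plain("in the"), loc, plain("."))
    siz <- entity_tokens(render_size(state$size_mm), "SIZE")
    sentences$size <- if (runif(1) < 0.5) {
      cat_pieces(plain("the largest lesion measures"), siz, plain("."))
    } else {
      cat_pieces(plain("measuring"), siz, plain("in diameter ."))
    }
    shp <- entity_tokens(surface_for(vocab, "SHAPE"), "SHAPE")
    sentences$shape <- cat_pieces(plain("the nodule appears"), shp,
                                  plain("in contour ."))
    rsk <- entity_tokens(surface_for(vocab, "RISK_LEVEL", state$risk),
                         "RISK_LEVEL")
    sentences$risk <- cat_pieces(plain("clinical context :"), rsk, plain("."))
  } else {
    nam <- entity_tokens(surface_for(vocab, "NODULE_NAME", "ABSENT"),
                         "NODULE_NAME")
    sentences$clear <- plain("the lungs are clear .")
    sentences$name <- cat_pieces(nam, plain("are identified ."))
  }
  pool <- distractor_pool()
  n_dis <- sample(1:2, 1)
  chosen <- sample(pool, n_dis)
  for (j in seq_along(chosen)) {
    sentences[[paste0("distractor", j)]] <- plain(chosen[j])
  }
  do.call(cat_pieces, sentences[sample(length(sentences))])
}

render_impression <- function(state, written_level, vocab) {
  head <- if (isTRUE(state$present)) {
    cat_pieces(plain("impression :"),
               entity_tokens(surface_for(vocab, "NODULE_NAME", "PRESENT"),
                             "NODULE_NAME"),
               plain("."))
  } else {
    cat_pieces(plain("impression :"),
               entity_tokens(surface_for(vocab, "NODULE_NAME", "ABSENT"),
                             "NODULE_NAME"),
               plain("."))
  }
  if (is.na(written_level)) return(head)
  fu <- entity_tokens(surface_for(vocab, "FOLLOWUP", written_level),
                      "FOLLOWUP")
  cat_pieces(head, plain("recommend :"), fu, plain("."))
}

draw_written_level <- function(gold_level, behavior) {
  row <- behavior[behavior$level == gold_level, ]
  if (nrow(row) != 1) {
    stop_bad_arg("behavior profile has no row for level %s", gold_level)
  }
  u <- runif(1)
  all_levels <- recommendation_levels()$level
  if (gold_level == "NOT_APPLICABLE") {
    if (u < row$p_correct + row$p_omit) NA_character_ else
      sample(all_levels, 1)
  } else if (u < row$p_correct) {
    gold_level
  } else if (u < row$p_correct + row$p_omit) {
    NA_character_
  } else {
    sample(setdiff(all_levels, gold_level), 1)
  }
}

render_report_impl <- function(report_id, state, vocab, behavior) {
  gold_level <- if ("gold_level" %in% names(state)) state$gold_level else
    oracle_recommend(state)
  written <- draw_written_level(gold_level, behavior)
  f <- render_findings(state, vocab)
  i <- render_impression(state, written, vocab)
  report <- tibble::tibble(report_id = report_id,
                           findings = paste(f$tokens, collapse = " "),
                           impression = paste(i$tokens, collapse = " "),
                           meta = list(character()))
  annotation <- tibble::tibble(report_id = report_id,
                               tokens = list(c(f$tokens, i$tokens)),
                               tags = list(c(f$tags, i$tags)))
  gold <- dplyr::bind_cols(
    tibble::tibble(report_id = report_id),
    state[c("present", "solidity", "size_mm", "size_bin", "quantity",
            "risk")],
    tibble::tibble(gold_level = gold_level, written_level = written))
  list(report = report, annotation = annotation, gold = gold)
}

#' Render one synthetic report
#'
#' Turns a nodule state into a findings/impression report with gold BIO
#' annotation: the findings contain one surface form per filled slot (plus
#' a shape, a location and distractor sentences); the impression restates
#' the nodule and, depending on the behavior profile, the correct
#' recommendation, none, or a wrong one.
#'
#' @param state one-row state tibble (see [sample_states()]).
#' @param vocab catalog tibble.
#' @param behavior behavior profile (see [default_behavior()]).
#' @param report_id identifier for the generated report.
#' @param seed integer seed, or `NULL` to use the current RNG stream.
#' @return list with elements `report`, `annotation`, `gold`.
#' @export
render_report <- function(state, vocab = default_vocabulary(),
                          behavior = default_behavior(),
                          report_id = "R00001", seed = NULL) {
  with_seed_or_not(seed,
                   render_report_impl(report_id, state, vocab, behavior))
}

#' Generate a synthetic annotated corpus
#'
#' Draws `n` nodule states, renders each into a report with gold BIO
#' annotation, and records the gold table (state slots, oracle
#' recommendation level, and the level actually written into the
#' impression, if any). Byte-identical for a fixed seed.
#'
#' @param n number of reports (>= 1).
#' @param seed integer seed.
#' @param vocab catalog tibble (see [default_vocabulary()]).
#' @param behavior behavior profile (see [default_behavior()]).
#' @param state_weights state distribution (see
#'   [default_state_weights()]).
#' @return object of class `nodule_corpus`: list with tibbles `reports`,
#'   `annotations`, `gold`.
#' @export
#' @examples
#' corp <- generate_corpus(5, seed = 42)
#' corp$reports$findings[1]
generate_corpus <- function(n, seed = NULL, vocab = default_vocabulary(),
                            behavior = default_behavior(),
                            state_weights = default_state_weights()) {
  if (!is.numeric(n) || n < 1) stop_bad_arg("n must be >= 1")
  n <- as.integer(n)
  with_seed_or_not(seed, {
    states <- sample_states_impl(n, state_weights)
    rows <- purrr::map(seq_len(n), function(i) {
      render_report_impl(sprintf("R%05d", i), states[i, ], vocab, behavior)
    })
    structure(list(reports = dplyr::bind_rows(purrr::map(rows, "report")),
                   annotations = dplyr::bind_rows(purrr::map(rows,
                                                             "annotation")),
                   gold = dplyr::bind_rows(purrr::map(rows, "gold"))),
              class = "nodule_corpus")
  })
}

#' @export
print.nodule_corpus <- function(x, ...) {
  cat(sprintf("<nodule_corpus: %d reports>\n", nrow(x$reports)))
  tb <- table(x$gold$gold_level)
  for (nm in names(tb)) cat(sprintf("  %-15s %d\n", nm, tb[[nm]]))
  invisible(x)
}

#' Gold mentions of an annotated corpus
#'
#' Reconstructs the typed mention spans (with character offsets into the
#' report's findings+impression text) from the gold BIO annotation.
#'
#' @param corpus a `nodule_corpus`, or an annotations tibble.
#' @return mentions tibble as in [predict.ner_model()].
#' @export
gold_mentions <- function(corpus) {
  ann <- if (inherits(corpus, "nodule_corpus")) corpus$annotations else corpus
  rows <- purrr::pmap(ann[c("report_id", "tokens", "tags")],
                      function(report_id, tokens, tags) {
                        text <- paste(tokens, collapse = " ")
                        tok <- tokenize_text(text)
                        mentions_from_tagged(report_id, tok, tags)
                      })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_mentions() else out
}
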