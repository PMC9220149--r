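#' Hyperparameters for the BiLSTM+CRF labeler
#'
#' Defaults are sized for a few-hundred-type synthetic vocabulary and
#' CPU-only training: the encoder capacity needed to separate templated
#' clinical phrasing is modest, so a 32-dimensional embedding and 64 hidden
#' units per direction train in minutes while leaving headroom above the
#' dictionary baseline. All values are configuration, not code.
#'
#' @param embedding_dim token embedding size.
#' @param hidden_dim LSTM hidden units per direction.
#' @param dropout dropout rate on the concatenated hidden states.
#' @param learning_rate Adam step size.
#' @param batch_size sequences per gradient step.
#' @param max_epochs upper bound on training epochs.
#' @param patience epochs without validation improvement before stopping.
#' @return named list of hyperparameters.
#' @export
ner_hyperparams <- function(embedding_dim = 32, hidden_dim = 64,
                            dropout = 0.3, learning_rate = 0.003,
                            batch_size = 8, max_epochs = 30, patience = 5) {
  list(embedding_dim = embedding_dim, hidden_dim = hidden_dim,
       dropout = dropout, learning_rate = learning_rate,
       batch_size = batch_size, max_epochs = max_epochs, patience = patience)
}

encode_tokens <- function(tokens, token_vocab) {
  idx <- match(tokens, token_vocab)
  idx[is.na(idx)] <- 1L # <unk>
  idx - 1L
}

encode_tags <- function(tags, tagset) {
  idx <- match(tags, tagset)
  if (anyNA(idx)) {
    stop_bad_arg("unknown tag(s): %s",
                 paste(unique(tags[is.na(idx)]), collapse = ", "))
  }
  idx - 1L
}

init_params <- function(hp, n_vocab, n_tags, seed) {
  d <- hp$embedding_dim
  h <- hp$hidden_dim
  k <- n_tags
  with_seed_or_not(seed, {
    rmat <- function(r, c, sd) matrix(rnorm(r * c, sd = sd), r, c)
    bf <- rep(0, 4 * h)
    bf[(h + 1):(2 * h)] <- 1 # forget-gate bias
    list(E = rmat(d, n_vocab, 0.1),
         Wf = rmat(4 * h, d, sqrt(1 / d)), Uf = rmat(4 * h, h, sqrt(1 / h)),
         bf = bf,
         Wb = rmat(4 * h, d, sqrt(1 / d)), Ub = rmat(4 * h, h, sqrt(1 / h)),
         bb = bf,
         Wp = rmat(k, 2 * h, sqrt(1 / (2 * h))), bp = rep(0, k),
         Tr = matrix(0, k + 2, k + 2))
  })
}

init_adam <- function(params) {
  st <- purrr::flatten(purrr::map(
    c("E", "Wf", "Uf", "bf", "Wb", "Ub", "bb", "Wp", "bp", "Tr"),
    function(nm) {
      z <- params[[nm]] * 0
      stats::setNames(list(z, z), paste0(c("m", "v"), nm))
    }))
  c(st, list(step = 0))
}

# entity-level micro F1 between two lists of tag vectors
micro_f1_tags <- function(gold_tags, pred_tags) {
  counts <- purrr::map2(gold_tags, pred_tags, function(g, p) {
    gs <- tags_to_mentions(seq_along(g), g)
    ps <- tags_to_mentions(seq_along(p), p)
    gk <- paste(gs$type, gs$token_start, gs$token_end)
    pk <- paste(ps$type, ps$token_start, ps$token_end)
    tp <- length(intersect(gk, pk))
    c(tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
  })
  s <- Reduce(`+`, counts)
  p <- if (s[["tp"]] + s[["fp"]] > 0) s[["tp"]] / (s[["tp"]] + s[["fp"]]) else 0
  r <- if (s[["tp"]] + s[["fn"]] > 0) s[["tp"]] / (s[["tp"]] + s[["fn"]]) else 0
  if (p + r > 0) 2 * p * r / (p + r) else 0
}

#' Train the BiLSTM+CRF entity labeler
#'
#' Fits a bidirectional LSTM encoder with a linear-chain CRF output layer
#' on BIO-annotated token sequences. Token embeddings are trained from
#' scratch; the transition matrix carries a hard BIO mask so decoded
#' output is valid by construction. After each epoch the entity-level
#' micro-F1 on the validation set is computed; training stops when it has
#' not improved for `patience` epochs and the best-scoring parameters are
#' returned. Deterministic given `seed` (single-threaded).
#'
#' @param train,validation annotations tibbles (`report_id`, `tokens`,
#'   `tags`; see [read_bio()]). `validation = NULL` disables early
#'   stopping.
#' @param hyperparams see [ner_hyperparams()].
#' @param seed integer seed for initialization, shuffling and dropout.
#' @param tagset BIO tag set (default [nodule_tagset()]).
#' @param quiet suppress per-epoch progress messages.
#' @return object of class `ner_model`.
#' @export
ner_train <- function(train, validation = NULL,
                      hyperparams = ner_hyperparams(), seed = 1,
                      tagset = nodule_tagset(), quiet = TRUE) {
  assert_columns(train, c("report_id", "tokens", "tags"))
  if (nrow(train) == 0) stop_bad_arg("training set is empty")
  hp <- hyperparams
  token_vocab <- c("<unk>", sort(unique(unlist(train$tokens))))
  if (length(token_vocab) <= 1) stop_bad_arg("empty token vocabulary")
  seqs <- purrr::map(train$tokens, encode_tokens, token_vocab = token_vocab)
  tags <- purrr::map(train$tags, encode_tags, tagset = tagset)
  allowed <- (is.finite(bio_transition_mask(tagset))) * 1
  params <- init_params(hp, length(token_vocab), length(tagset), seed)
  adam <- init_adam(params)
  val_seqs <- NULL
  if (!is.null(validation) && nrow(validation) > 0) {
    val_seqs <- purrr::map(validation$tokens, encode_tokens,
                           token_vocab = token_vocab)
  }
  best <- list(f1 = -Inf, params = params, epoch = 0)
  wait <- 0
  history <- vector("list", hp$max_epochs)
  for (epoch in seq_len(hp$max_epochs)) {
    res <- cpp_crf_epoch(params, adam, seqs, tags, allowed, hp$dropout,
                         hp$learning_rate, hp$batch_size,
                         as.integer((seed * 1000L + epoch) %% .Machine$integer.max))
    params <- res$params
    adam <- res$adam
    val_f1 <- NA_real_
    if (!is.null(val_seqs)) {
      paths <- cpp_crf_decode(params, val_seqs, allowed)
      pred <- purrr::map(paths, ~ tagset[.x + 1])
      val_f1 <- micro_f1_tags(validation$tags, pred)
    }
    history[[epoch]] <- tibble::tibble(epoch = epoch,
                                       train_nll = res$mean_nll,
                                       val_f1 = val_f1)
    if (!quiet) {
      inform(sprintf("epoch %d: train nll %.4f, val F1 %s", epoch,
                     res$mean_nll,
                     if (is.na(val_f1)) "-" else sprintf("%.4f", val_f1)))
    }
    if (!is.null(val_seqs)) {
      if (val_f1 > best$f1) {
        best <- list(f1 = val_f1, params = params, epoch = epoch)
        wait <- 0
      } else {
        wait <- wait + 1
        if (wait >= hp$patience) break
      }
      if (val_f1 == 1) break # nothing left to improve
    } else {
      best <- list(f1 = NA_real_, params = params, epoch = epoch)
    }
  }
  structure(list(params = best$params, token_vocab = token_vocab,
                 tagset = tagset, allowed = allowed, hyperparams = hp,
                 history = dplyr::bind_rows(history),
                 best_epoch = best$epoch, val_f1 = best$f1, seed = seed),
            class = "ner_model")
}

#' @export
print.ner_model <- function(x, ...) {
  cat("<ner_model: BiLSTM + CRF>\n")
  cat(sprintf("  vocab %d tokens, %d tags; embed %d, hidden %d/direction\n",
              length(x$token_vocab), length(x$tagset),
              x$hyperparams$embedding_dim, x$hyperparams$hidden_dim))
  cat(sprintf("  trained %d epoch(s); best epoch %d, validation F1 %s\n",
              nrow(x$history), x$best_epoch,
              if (is.na(x$val_f1)) "-" else sprintf("%.4f", x$val_f1)))
  invisible(x)
}

#' @export
glance.ner_model <- function(x, ...) {
  tibble::tibble(epochs = nrow(x$history), best_epoch = x$best_epoch,
                 val_f1 = x$val_f1,
                 n_tokens = length(x$token_vocab))
}

#' @export
tidy.ner_model <- function(x, ...) x$history

resolve_texts <- function(newdata, text) {
  if (is.character(newdata)) {
    ids <- names(newdata) %||% as.character(seq_along(newdata))
    tibble::tibble(report_id = ids, .text = unname(newdata))
  } else {
    assert_columns(newdata, c("report_id", text))
    tibble::tibble(report_id = newdata$report_id, .text = newdata[[text]])
  }
}

mentions_from_tagged <- function(report_id, tok, tags) {
  m <- tags_to_mentions(tok$token, tags, tok$start, tok$end)
  if (nrow(m) == 0) return(NULL)
  dplyr::mutate(m, report_id = report_id, .before = 1)
}

empty_mentions <- function() {
  tibble::tibble(report_id = character(), type = character(),
                 token_start = integer(), token_end = integer(),
                 text = character(), start = integer(), end = integer())
}

#' Extract entity mentions from report text
#'
#' Runs the labeler over each text, Viterbi-decodes the BIO tags and
#' converts tag runs into typed spans with 0-based, end-exclusive
#' character offsets.
#'
#' @param object a `ner_model` (or [dictionary_tagger()]).
#' @param newdata a reports tibble or a (optionally named) character
#'   vector of texts.
#' @param text column of `newdata` holding the text (default
#'   `"findings"`).
#' @param ... unused.
#' @return mentions tibble: `report_id`, `type`, `token_start`,
#'   `token_end`, `text`, `start`, `end`.
#' @export
predict.ner_model <- function(object, newdata, text = "findings", ...) {
  df <- resolve_texts(newdata, text)
  toks <- purrr::map(df$.text, tokenize_text)
  seqs <- purrr::map(toks, ~ encode_tokens(.x$token, object$token_vocab))
  paths <- cpp_crf_decode(object$params, seqs, object$allowed)
  rows <- purrr::pmap(list(df$report_id, toks, paths),
                      function(id, tok, path) {
                        mentions_from_tagged(id, tok, object$tagset[path + 1])
                      })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_mentions() else out
}

#' Predict BIO tags for already-tokenized sequences
#'
#' @param model a `ner_model` or `dictionary_tagger`.
#' @param annotations tibble with `report_id` and `tokens` list-column.
#' @return the tibble with a `tags` list-column of predicted tags.
#' @export
predict_tags <- function(model, annotations) UseMethod("predict_tags")

#' @export
predict_tags.ner_model <- function(model, annotations) {
  seqs <- purrr::map(annotations$tokens, encode_tokens,
                     token_vocab = model$token_vocab)
  paths <- cpp_crf_decode(model$params, seqs, model$allowed)
  dplyr::mutate(annotations[c("report_id", "tokens")],
                tags = purrr::map(paths, ~ model$tagset[.x + 1]))
}

#' Dictionary-matching baseline tagger
#'
#' Greedy longest-match of catalog surface forms over the token sequence
#' (case-insensitive), plus a numeric rule for sizes (a number carrying or
#' followed by a `mm`/`cm` unit). Serves as the independent baseline the
#' learned labeler must beat, and as a deterministic extraction model
#' where NER quality is not under study.
#'
#' @param catalog catalog tibble (default [default_vocabulary()]).
#' @return object of class `dictionary_tagger`.
#' @export
dictionary_tagger <- function(catalog = default_vocabulary()) {
  entries <- catalog |>
    dplyr::mutate(toks = purrr::map(.data$surface,
                                    ~ tolower(tokenize_tokens(.x))),
                  len = lengths(.data$toks)) |>
    dplyr::arrange(dplyr::desc(.data$len))
  structure(list(entries = entries), class = "dictionary_tagger")
}

dictionary_match <- function(tagger, tokens) {
  n <- length(tokens)
  tags <- rep("O", n)
  low <- unname(tolower(tokens))
  entries <- tagger$entries
  is_size <- grepl("^[0-9]+(\\.[0-9]+)?(×[0-9]+(\\.[0-9]+)?)*(mm|cm)$", low)
  is_num <- grepl("^[0-9]+(\\.[0-9]+)?(×[0-9]+(\\.[0-9]+)?)*$", low)
  is_unit <- low %in% c("mm", "cm")
  pos <- 1L
  while (pos <= n) {
    matched <- FALSE
    for (e in seq_len(nrow(entries))) {
      len <- entries$len[e]
      if (pos + len - 1 > n) next
      if (identical(low[pos:(pos + len - 1)], entries$toks[[e]])) {
        tags[pos:(pos + len - 1)] <- c(paste0("B-", entries$type[e]),
                                       rep(paste0("I-", entries$type[e]),
                                           len - 1))
        pos <- pos + len
        matched <- TRUE
        break
      }
    }
    if (matched) next
    if (is_size[pos]) {
      tags[pos] <- "B-SIZE"
      pos <- pos + 1L
    } else if (is_num[pos] && pos < n && is_unit[pos + 1]) {
      tags[pos] <- "B-SIZE"
      tags[pos + 1] <- "I-SIZE"
      pos <- pos + 2L
    } else {
      pos <- pos + 1L
    }
  }
  tags
}

#' @rdname predict.ner_model
#' @export
predict.dictionary_tagger <- function(object, newdata, text = "findings",
                                      ...) {
  df <- resolve_texts(newdata, text)
  rows <- purrr::map2(df$report_id, df$.text, function(id, x) {
    tok <- tokenize_text(x)
    mentions_from_tagged(id, tok, dictionary_match(object, tok$token))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0) empty_mentions() else out
}

#' @export
predict_tags.dictionary_tagger <- function(model, annotations) {
  dplyr::mutate(annotations[c("report_id", "tokens")],
                tags = purrr::map(annotations$tokens,
                                  ~ dictionary_match(model, .x)))
}

#' Evaluate entity extraction
#'
#' Compares predicted BIO tag sequences against gold annotations keyed by
#' the same report ids. Precision, recall and F1 are entity-level over
#' exact (span, type) matches, with precision defined as 0 when there are
#' no predictions; accuracy is token-level (per type: over tokens whose
#' gold tag belongs to that type; total: over all tokens). The `number`
#' column reports the per-type count of distinct catalog entities.
#'
#' @param gold,predicted annotations tibbles (`report_id`, `tokens`,
#'   `tags`).
#' @param catalog catalog tibble used for the `number` column.
#' @return tibble of class `ner_metrics`: one row per entity type plus a
#'   `Total` micro-average row; columns `entity_type`, `accuracy`,
#'   `precision`, `recall`, `f1`, `number`.
#' @export
evaluate_ner <- function(gold, predicted, catalog = default_vocabulary()) {
  assert_columns(gold, c("report_id", "tags"))
  assert_columns(predicted, c("report_id", "tags"))
  if (!setequal(gold$report_id, predicted$report_id)) {
    stop_bad_arg("gold and predicted annotations cover different report ids")
  }
  predicted <- predicted[match(gold$report_id, predicted$report_id), ]
  bad <- setdiff(unique(unlist(predicted$tags)), nodule_tagset())
  if (length(bad) > 0) {
    stop_bad_arg("predictions contain unknown tag(s): %s",
                 paste(bad, collapse = ", "))
  }
  types <- entity_types()
  per_seq <- purrr::map2(gold$tags, predicted$tags, function(g, p) {
    if (length(g) != length(p)) {
      stop_bad_arg("gold and predicted tag sequences differ in length")
    }
    gs <- tags_to_mentions(seq_along(g), g)
    ps <- tags_to_mentions(seq_along(p), p)
    gk <- paste(gs$type, gs$token_start, gs$token_end)
    pk <- paste(ps$type, ps$token_start, ps$token_end)
    list(g = g, p = p,
         gs = tibble::tibble(type = gs$type, key = gk),
         ps = tibble::tibble(type = ps$type, key = pk),
         hit = tibble::tibble(type = gs$type[gk %in% pk],
                              key = gk[gk %in% pk]))
  })
  g_all <- unlist(purrr::map(per_seq, "g"))
  p_all <- unlist(purrr::map(per_seq, "p"))
  gs_all <- dplyr::bind_rows(purrr::map(per_seq, "gs"))
  ps_all <- dplyr::bind_rows(purrr::map(per_seq, "ps"))
  hit_all <- dplyr::bind_rows(purrr::map(per_seq, "hit"))
  counts <- dplyr::count(catalog, .data$type)
  row_for <- function(ty) {
    in_ty <- if (ty == "Total") rep(TRUE, length(g_all)) else
      !is.na(tag_type(g_all)) & tag_type(g_all) == ty
    acc <- if (any(in_ty)) mean(g_all[in_ty] == p_all[in_ty]) else NA_real_
    tp <- if (ty == "Total") nrow(hit_all) else sum(hit_all$type == ty)
    np <- if (ty == "Total") nrow(ps_all) else sum(ps_all$type == ty)
    ng <- if (ty == "Total") nrow(gs_all) else sum(gs_all$type == ty)
    p <- if (np > 0) tp / np else 0
    r <- if (ng > 0) tp / ng else 0
    f1 <- if (p + r > 0) 2 * p * r / (p + r) else 0
    num <- if (ty %in% c("Total")) sum(counts$n) else
      if (ty == "SIZE") NA_integer_ else
        counts$n[match(ty, counts$type)]
    tibble::tibble(entity_type = ty, accuracy = acc, precision = p,
                   recall = r, f1 = f1, number = num)
  }
  out <- dplyr::bind_rows(purrr::map(c(types, "Total"), row_for))
  structure(out, class = c("ner_metrics", class(out)))
}

#' @export
glance.ner_metrics <- function(x, ...) {
  tot <- dplyr::filter(x, .data$entity_type == "Total")
  tibble::tibble(accuracy = tot$accuracy, precision = tot$precision,
                 recall = tot$recall, f1 = tot$f1)
}

#' Write Table-style NER metrics to CSV
#'
#' @param metrics a `ner_metrics` tibble.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_ner_metrics <- function(metrics, path) {
  write.csv(as.data.frame(metrics), path, row.names = FALSE, na = "")
  invisible(path)
}
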