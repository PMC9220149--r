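#' Entity types and BIO tag set
#'
#' The labeler recognises eight entity types: seven practical nodule
#' attributes (location, shape, nodule name, solidity, quantity, risk level,
#' size) plus the follow-up recommendation. `nodule_tagset()` is the
#' corresponding 17-tag BIO scheme (`O` plus `B-`/`I-` per type).
#'
#' @return `entity_types()`: character vector of the 8 entity type names.
#'   `nodule_tagset()`: character vector of the 17 BIO tags, `O` first.
#' @export
#' @examples
#' entity_types()
#' nodule_tagset()
entity_types <- function() {
  c("LOCATION", "SHAPE", "NODULE_NAME", "SOLIDITY",
    "QUANTITY", "RISK_LEVEL", "SIZE", "FOLLOWUP")
}

#' @rdname entity_types
#' @export
nodule_tagset <- function() {
  c("O", as.vector(rbind(paste0("B-", entity_types()),
                         paste0("I-", entity_types()))))
}

tag_type <- function(tags) {
  ifelse(tags == "O", NA_character_, sub("^[BI]-", "", tags))
}

#' BIO transition mask
#'
#' Builds the additive transition mask of a linear-chain CRF over a BIO tag
#' set: allowed transitions score 0, forbidden ones `-Inf`. The matrix has
#' two virtual states appended, `START` (row used for the transition into
#' the first tag) and `STOP` (column used for the transition out of the last
#' tag). Forbidden are: `I-X` after `O`, after `B-Y`/`I-Y` with `Y != X`,
#' and directly after `START`; plus anything into `START` or out of `STOP`.
#'
#' @param tagset character vector of BIO tags (default [nodule_tagset()]).
#' @return numeric `(K+2) x (K+2)` matrix (`K = length(tagset)`) with
#'   dimnames `c(tagset, "START", "STOP")`; entries 0 or `-Inf`.
#' @export
#' @examples
#' m <- bio_transition_mask(c("O", "B-SIZE", "I-SIZE"))
#' m["O", "I-SIZE"]        # -Inf: I- may not follow O
#' m["B-SIZE", "I-SIZE"]   # 0
bio_transition_mask <- function(tagset = nodule_tagset()) {
  k <- length(tagset)
  states <- c(tagset, "START", "STOP")
  mask <- matrix(0, k + 2, k + 2, dimnames = list(states, states))
  types <- tag_type(tagset)
  prefix <- substr(tagset, 1, 1)
  for (j in seq_len(k)) {
    if (prefix[j] == "I") {
      ok_from <- prefix %in% c("B", "I") & types == types[j]
      mask[seq_len(k), j][!ok_from] <- -Inf
      mask["START", j] <- -Inf
    }
  }
  mask[, "START"] <- -Inf
  mask["STOP", ] <- -Inf
  mask["START", "STOP"] <- -Inf   # empty sequences are not scored
  mask
}

# validate one BIO tag sequence against a tag set; returns NULL if valid,
# otherwise a message describing the first violation
bio_violation <- function(tags, tagset = nodule_tagset()) {
  bad <- setdiff(tags, tagset)
  if (length(bad) > 0) {
    return(sprintf("unknown tag(s): %s", paste(unique(bad), collapse = ", ")))
  }
  prev <- c("O", tags[-length(tags)])
  types <- tag_type(tags)
  prev_types <- tag_type(prev)
  is_i <- startsWith(tags, "I-")
  bad_pos <- which(is_i & (prev == "O" | prev_types != types))
  if (length(bad_pos) > 0) {
    p <- bad_pos[1]
    return(sprintf("invalid BIO transition %s -> %s at position %d",
                   if (p == 1) "START" else prev[p], tags[p], p))
  }
  NULL
}

#' Convert BIO-tagged tokens to entity mentions
#'
#' Collapses maximal `B-X I-X ...` runs into typed spans. When token
#' character offsets are supplied the mention carries 0-based,
#' end-exclusive character offsets into the source text; otherwise only
#' token indices are returned.
#'
#' @param tokens character vector of tokens.
#' @param tags BIO tags, same length as `tokens`.
#' @param starts,ends optional integer vectors of 0-based/end-exclusive
#'   character offsets per token (as returned by [tokenize_text()]).
#' @return tibble with columns `type`, `token_start`, `token_end` (1-based,
#'   inclusive), `text`, and — when offsets were given — `start`, `end`.
#' @export
#' @examples
#' tags_to_mentions(c("a", "solid", "nodule"), c("O", "B-SOLIDITY", "O"))
tags_to_mentions <- function(tokens, tags, starts = NULL, ends = NULL) {
  if (length(tokens) != length(tags)) {
    stop_bad_arg("tokens (%d) and tags (%d) differ in length",
                 length(tokens), length(tags))
  }
  is_b <- startsWith(tags, "B-")
  run_id <- cumsum(is_b | tags == "O")
  keep <- tags != "O"
  if (!any(keep)) {
    out <- tibble::tibble(type = character(), token_start = integer(),
                          token_end = integer(), text = character())
    if (!is.null(starts)) {
      out$start <- integer()
      out$end <- integer()
    }
    return(out)
  }
  idx <- split(which(keep), run_id[keep])
  rows <- purrr::map(idx, function(ii) {
    tibble::tibble(type = tag_type(tags[ii[1]]),
                   token_start = ii[1], token_end = ii[length(ii)],
                   text = paste(tokens[ii], collapse = " "))
  })
  out <- dplyr::bind_rows(rows)
  if (!is.null(starts)) {
    out$start <- starts[out$token_start]
    out$end <- ends[out$token_end]
  }
  out
}

# inverse of tags_to_mentions for gold construction: token-index spans -> tags
mentions_to_tags <- function(n_tokens, mentions) {
  tags <- rep("O", n_tokens)
  for (i in seq_len(nrow(mentions))) {
    span <- mentions$token_start[i]:mentions$token_end[i]
    tags[span] <- c(paste0("B-", mentions$type[i]),
                    rep(paste0("I-", mentions$type[i]), length(span) - 1))
  }
  tags
}
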