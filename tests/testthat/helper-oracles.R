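# Independent brute-force oracles for the CRF operations: enumerate every
# tag path explicitly and score it by direct summation. Deliberately kept
# free of any package internals beyond the argument conventions.

enum_paths <- function(n_pos, n_tags) {
  as.matrix(expand.grid(rep(list(seq_len(n_tags)), n_pos)))
}

enum_path_score <- function(emissions, transitions, path) {
  k <- ncol(emissions)
  s <- transitions[k + 1, path[1]]
  for (t in seq_along(path)) {
    s <- s + emissions[t, path[t]]
    if (t > 1) s <- s + transitions[path[t - 1], path[t]]
  }
  s + transitions[path[length(path)], k + 2]
}

enum_all_scores <- function(emissions, transitions) {
  n_pos <- nrow(emissions)
  k <- ncol(emissions)
  paths <- enum_paths(n_pos, k)
  s <- transitions[k + 1, paths[, 1]] + transitions[cbind(paths[, n_pos], k + 2)]
  for (t in seq_len(n_pos)) {
    s <- s + emissions[t, paths[, t]]
    if (t > 1) s <- s + transitions[cbind(paths[, t - 1], paths[, t])]
  }
  s
}

enum_log_partition <- function(emissions, transitions) {
  s <- enum_all_scores(emissions, transitions)
  m <- max(s)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(s - m)))
}

enum_best_score <- function(emissions, transitions) {
  max(enum_all_scores(emissions, transitions))
}

# random CRF instance; with prob 1/2 a few transitions are masked to -Inf
random_crf_instance <- function(n_pos, n_tags, mask_some = TRUE) {
  em <- matrix(runif(n_pos * n_tags, -2, 2), n_pos, n_tags)
  tr <- matrix(runif((n_tags + 2)^2, -1, 1), n_tags + 2, n_tags + 2)
  tr[, n_tags + 1] <- -Inf
  tr[n_tags + 2, ] <- -Inf
  if (mask_some && runif(1) < 0.5) {
    ij <- cbind(sample(n_tags, 2, replace = TRUE),
                sample(n_tags, 2, replace = TRUE))
    tr[ij] <- -Inf
  }
  list(emissions = em, transitions = tr)
}

# small corpora shared across tests (built once per test run)
tiny_corpus <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_corpus(60, seed = 1003)
    cache
  }
})
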