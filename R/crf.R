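#' Linear-chain CRF primitives
#'
#' Reference implementations of the scoring, normalization and decoding
#' operations of a linear-chain conditional random field. A tag path's
#' score is the sum of its per-position emission scores and its transition
#' scores, including the transitions out of the virtual `START` state and
#' into the virtual `STOP` state. Transitions forbidden by a mask (such as
#' the BIO mask of [bio_transition_mask()]) carry score `-Inf` and are
#' never selected by decoding.
#'
#' `crf_score()` scores one path; `crf_log_partition()` is the forward
#' algorithm (log of the summed exponentiated scores of all valid paths,
#' computed in log-space); `crf_nll()` is the negative log-likelihood
#' `log_partition - score`; `viterbi_decode()` returns the maximum-scoring
#' path, breaking exact ties toward the lowest tag index at each backtrack
#' step.
#'
#' @param emissions numeric `T x K` matrix: per-position score for each of
#'   the `K` tags.
#' @param transitions numeric `(K+2) x (K+2)` matrix; row/column `K+1` is
#'   `START`, `K+2` is `STOP` (rows = from, columns = to). May contain
#'   `-Inf` for forbidden transitions.
#' @param path integer vector of tag indices (1-based), one per position.
#' @return `crf_score()`, `crf_log_partition()`, `crf_nll()`: a single
#'   numeric; `viterbi_decode()`: an integer path.
#' @export
#' @examples
#' em <- matrix(c(0, 0), nrow = 1)            # length-1 sequence, 2 tags
#' tr <- matrix(0, 4, 4)
#' crf_log_partition(em, tr)                  # log(2)
#' viterbi_decode(em, tr)
crf_score <- function(emissions, transitions, path) {
  k <- ncol(emissions)
  n <- nrow(emissions)
  check_crf_args(emissions, transitions)
  if (length(path) != n) {
    stop_bad_arg("path length (%d) does not match emission rows (%d)",
                 length(path), n)
  }
  if (any(path < 1 | path > k)) stop_bad_arg("path contains tags outside 1..%d", k)
  s <- transitions[k + 1, path[1]] +
    sum(emissions[cbind(seq_len(n), path)]) +
    transitions[path[n], k + 2]
  if (n > 1) s <- s + sum(transitions[cbind(path[-n], path[-1])])
  s
}

#' @rdname crf_score
#' @export
crf_log_partition <- function(emissions, transitions) {
  k <- ncol(emissions)
  n <- nrow(emissions)
  check_crf_args(emissions, transitions)
  if (any(!is.finite(emissions))) stop_bad_arg("emissions must be finite")
  alpha <- transitions[k + 1, seq_len(k)] + emissions[1, ]
  if (n > 1) {
    for (t in 2:n) {
      alpha <- vapply(seq_len(k), function(j) {
        logsumexp(alpha + transitions[seq_len(k), j])
      }, numeric(1)) + emissions[t, ]
    }
  }
  logsumexp(alpha + transitions[seq_len(k), k + 2])
}

#' @rdname crf_score
#' @export
crf_nll <- function(emissions, transitions, path) {
  s <- crf_score(emissions, transitions, path)
  if (!is.finite(s)) {
    stop_bad_arg("gold path crosses a forbidden (-Inf) transition")
  }
  nll <- crf_log_partition(emissions, transitions) - s
  # guard against tiny negative values from floating-point cancellation
  if (nll < 0 && nll > -1e-9) nll <- 0
  nll
}

#' @rdname crf_score
#' @export
viterbi_decode <- function(emissions, transitions) {
  k <- ncol(emissions)
  n <- nrow(emissions)
  check_crf_args(emissions, transitions)
  if (any(!is.finite(emissions))) stop_bad_arg("emissions must be finite")
  delta <- transitions[k + 1, seq_len(k)] + emissions[1, ]
  psi <- matrix(0L, nrow = n, ncol = k)
  if (n > 1) {
    for (t in 2:n) {
      m <- delta + transitions[seq_len(k), seq_len(k)] # m[i, j]
      best <- apply(m, 2, which.max)                   # first max: lowest index
      delta <- m[cbind(best, seq_len(k))] + emissions[t, ]
      psi[t, ] <- best
    }
  }
  final <- delta + transitions[seq_len(k), k + 2]
  path <- integer(n)
  path[n] <- which.max(final)
  if (n > 1) {
    for (t in n:2) path[t - 1] <- psi[t, path[t]]
  }
  path
}

check_crf_args <- function(emissions, transitions) {
  if (!is.matrix(emissions) || nrow(emissions) < 1) {
    stop_bad_arg("emissions must be a matrix with at least one row")
  }
  k <- ncol(emissions)
  if (!is.matrix(transitions) || any(dim(transitions) != k + 2)) {
    stop_bad_arg("transitions must be a (K+2) x (K+2) matrix with K = %d", k)
  }
  invisible(TRUE)
}
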