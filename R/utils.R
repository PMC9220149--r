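# internal helpers shared across modules

# run `expr` under a fixed seed without disturbing the caller's RNG state;
# a NULL seed leaves the current RNG alone
with_seed_or_not <- function(seed, expr) {
  if (is.null(seed)) expr else withr::with_seed(as.integer(seed), expr)
}

stop_bad_arg <- function(msg, ...) abort(sprintf(msg, ...), class = "noduleaudit_error")

assert_columns <- function(df, cols, arg = deparse(substitute(df))) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    stop_bad_arg("`%s` is missing required column(s): %s", arg,
                 paste(missing, collapse = ", "))
  }
  invisible(df)
}

# log-sum-exp that tolerates -Inf entries (empty/forbidden mass)
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(x - m)))
}
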