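# Internal helpers shared across modules.

#' Derive a reproducible sub-seed for a named random stream
#'
#' All stochastic stages draw their randomness from one master seed through
#' named streams (e.g. "events" vs "noise"), so that one source of randomness
#' can be varied while the others stay fixed.
#'
#' @param seed master integer seed.
#' @param stream short stream name.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @keywords internal
stream_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  m <- 2147483647  # 2^31 - 1, Mersenne prime modulus
  h <- (seed %% m)
  for (ch in utf8ToInt(stream)) {
    h <- (h * 131 + ch) %% m
  }
  as.integer(h)
}

# Evaluate expr with the RNG seeded locally, restoring global RNG state after.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Scalar checks with readable diagnostics.
check_scalar <- function(x, name, positive = FALSE, finite = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(sprintf("`%s` must be a single non-missing number", name), call. = FALSE)
  if (finite && !is.finite(x))
    stop(sprintf("`%s` must be finite", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("`%s` must be > 0 (got %g)", name, x), call. = FALSE)
  invisible(x)
}

# Standard error of the mean; NA for a single value.
se_mean <- function(x) {
  n <- sum(!is.na(x))
  if (n < 2L) return(NA_real_)
  stats::sd(x, na.rm = TRUE) / sqrt(n)
}

# Count sign changes ignoring exact zeros (a zero sample between opposite
# signs counts as one crossing).
count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  if (length(s) < 2L) return(0L)
  sum(diff(s) != 0)
}
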