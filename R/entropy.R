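#' Shannon entropy of a probability distribution, in bits
#'
#' `-sum(p * log2(p))` with the convention `0 * log(0) = 0`. The input must
#' be a valid distribution (nonnegative, summing to one within tolerance).
#' The result lies in `[0, log2(K)]` for `K` bins: zero iff degenerate,
#' maximal iff uniform.
#'
#' @param p numeric vector of probabilities.
#' @param tol tolerance on `sum(p) == 1`.
#' @return entropy in bits.
#' @export
#' @examples
#' shannon_entropy(rep(0.25, 4))          # 2 bits
#' shannon_entropy(c(0.5, 0.25, 0.25))    # 1.5 bits
shannon_entropy <- function(p, tol = 1e-8) {
  if (any(p < 0)) stop("probabilities must be nonnegative", call. = FALSE)
  if (abs(sum(p) - 1) > tol)
    stop(sprintf("probabilities sum to %.10g, not 1", sum(p)), call. = FALSE)
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Default log-spaced dwell-time bin edges
#'
#' Eight bins per decade from the sampling interval `dt` up to `t_max`,
#' shared across conditions so dwell entropies are directly comparable.
#'
#' @param dt shortest resolvable dwell in seconds (one sampling interval).
#' @param t_max upper edge in seconds.
#' @param bins_per_decade histogram resolution.
#' @return vector of strictly increasing edges in seconds.
#' @export
default_dwell_edges <- function(dt = 1e-4, t_max = 100, bins_per_decade = 8) {
  check_scalar(dt, "dt", positive = TRUE)
  check_scalar(t_max, "t_max", positive = TRUE)
  if (t_max <= dt) stop("`t_max` must exceed `dt`", call. = FALSE)
  n <- ceiling((log10(t_max) - log10(dt)) * bins_per_decade)
  10^seq(log10(dt), by = 1 / bins_per_decade, length.out = n + 1)
}

#' Normalized dwell-time histogram
#'
#' Pools open and closed dwell durations (the default; restrict with
#' `states`) and bins them on the supplied edges. Durations outside the
#' edge range are counted in the nearest end bin and reported through the
#' `n_clamped` field.
#'
#' @param dwells a [extract_dwell_times()] result (or any data frame with
#'   `state` and `duration` columns).
#' @param edges strictly increasing bin edges in seconds;
#'   [default_dwell_edges()] by default, anchored at the source sampling
#'   interval when known.
#' @param states which dwell states to include.
#' @return a `dwell_histogram`: list with `bin_edges`, `probabilities`,
#'   `counts`, `n`, `n_clamped`.
#' @export
dwell_histogram <- function(dwells, edges = NULL, states = c("O", "C")) {
  stopifnot(is.data.frame(dwells), all(c("state", "duration") %in% names(dwells)))
  if (is.null(edges)) {
    fs <- attr(dwells, "sampling_rate")
    dt <- if (is.null(fs)) 1e-4 else 1 / fs
    edges <- default_dwell_edges(dt = dt)
  }
  if (is.unsorted(edges, strictly = TRUE))
    stop("`edges` must be strictly increasing", call. = FALSE)
  d <- dwells$duration[dwells$state %in% states]
  if (length(d) == 0L) stop("no dwells to bin", call. = FALSE)
  k <- length(edges) - 1L
  idx <- findInterval(d, edges, rightmost.closed = TRUE)
  n_clamped <- sum(idx < 1L | idx > k)
  idx <- pmin(pmax(idx, 1L), k)
  counts <- tabulate(idx, nbins = k)
  structure(
    list(bin_edges = edges, probabilities = counts / sum(counts),
         counts = counts, n = length(d), n_clamped = n_clamped),
    class = "dwell_histogram")
}

#' Sample entropy of a numeric series
#'
#' SampEn is the negative natural logarithm of the conditional probability
#' that two subsequences similar for `m` points (Chebyshev distance within
#' `r`) remain similar at point `m + 1`. Low values mean regular,
#' predictable dynamics; high values mean irregular dynamics.
#'
#' Two normalizations are available. The default counts similar pairs over
#' all `N - m + 1` length-`m` templates with per-template denominator
#' `N - m` at both lengths. `variant = "richman"` is the canonical
#' Richman–Moorman form, restricting both counts to the `N - m` templates
#' that extend to length `m + 1` (the normalizers then cancel). The two
#' differ only in boundary templates and agree as `N` grows.
#'
#' When no similar pair extends to length `m + 1` the conditional
#' probability is zero and SampEn is undefined: the result is flagged
#' (`undefined = TRUE`, value `NA`), never infinite.
#'
#' @param x numeric series.
#' @param m embedding dimension (template length), default 2.
#' @param r similarity threshold in the units of `x`; commonly `0.2 * sd(x)`.
#' @param variant counting convention, see Details.
#' @return a `sampen_result`: list with `value` (natural-log units), `m`,
#'   `r`, `n`, `undefined`, `reason`, and the raw match counts.
#' @export
#' @examples
#' set.seed(1)
#' x <- runif(300)
#' sample_entropy(x, m = 2, r = 0.2 * sd(x))
sample_entropy <- function(x, m = 2L, r, variant = c("default", "richman")) {
  variant <- match.arg(variant)
  x <- as.numeric(x)
  n <- length(x)
  if (!is.numeric(m) || m < 1L) stop("`m` must be a positive integer", call. = FALSE)
  m <- as.integer(m)
  if (n <= m + 1L)
    stop(sprintf("series too short: need N > m + 1 (N = %d, m = %d)", n, m),
         call. = FALSE)
  check_scalar(r, "r")
  if (r <= 0) stop("`r` must be > 0", call. = FALSE)

  s <- sampen_counts_cpp(x, m, r)
  sm_full <- s[1]; sm_restr <- s[2]; sm1 <- s[3]
  if (variant == "default") {
    # ordered-pair means: B = 2*sm_full / ((N-m+1)(N-m)), A with one fewer
    # template at each length
    b <- 2 * sm_full / ((n - m + 1) * (n - m))
    a <- 2 * sm1 / ((n - m) * (n - m - 1))
  } else {
    b <- 2 * sm_restr / ((n - m) * (n - m - 1))
    a <- 2 * sm1 / ((n - m) * (n - m - 1))
  }
  undefined <- FALSE
  reason <- NA_character_
  value <- NA_real_
  if (b == 0) {
    undefined <- TRUE
    reason <- "no similar m-point templates (C^m = 0)"
  } else if (a == 0) {
    undefined <- TRUE
    reason <- "no similar (m+1)-point templates (C^(m+1) = 0)"
  } else {
    value <- -log(a / b)
  }
  structure(
    list(value = value, m = m, r = r, n = n, variant = variant,
         undefined = undefined, reason = reason,
         matches_m = if (variant == "default") sm_full else sm_restr,
         matches_m1 = sm1),
    class = "sampen_result")
}

#' @export
print.sampen_result <- function(x, ...) {
  if (isTRUE(x$undefined)) {
    cat(sprintf("<sampen_result> undefined (%s); m = %d, r = %.4g, N = %d\n",
                x$reason, x$m, x$r, x$n))
  } else {
    cat(sprintf("<sampen_result> SampEn = %.4f (m = %d, r = %.4g, N = %d)\n",
                x$value, x$m, x$r, x$n))
  }
  invisible(x)
}

#' Windowed sample entropy of a dwell-time series
#'
#' The interleaved dwell durations (raw, untransformed) are split into
#' non-overlapping windows of `window` values; SampEn is computed per
#' window with `r = r_factor` times that window's SD, and summarized as
#' mean plus standard error over windows. With fewer dwells than one
#' window, the whole series is used as a single window (with a warning).
#'
#' @param dwells a [extract_dwell_times()] result, or a numeric vector of
#'   dwell durations.
#' @param window window length in dwell counts (default 4000).
#' @param m embedding dimension.
#' @param r_factor similarity threshold as a multiple of the window SD.
#' @param variant see [sample_entropy()].
#' @return a `sampen_windowed`: list with `mean`, `se`, `n_windows`,
#'   `values` (per defined window), `n_undefined`, and the parameters.
#' @export
windowed_sample_entropy <- function(dwells, window = 4000L, m = 2L,
                                    r_factor = 0.2,
                                    variant = c("default", "richman")) {
  variant <- match.arg(variant)
  x <- if (is.data.frame(dwells)) dwells$duration else as.numeric(dwells)
  check_scalar(window, "window", positive = TRUE)
  check_scalar(r_factor, "r_factor", positive = TRUE)
  n <- length(x)
  n_win <- n %/% window
  if (n_win == 0L) {
    warning(sprintf(
      "only %d dwells (< one window of %d): falling back to a single window",
      n, window), call. = FALSE)
    pieces <- list(x)
  } else {
    pieces <- lapply(seq_len(n_win), function(i)
      x[((i - 1L) * window + 1L):(i * window)])
  }
  res <- lapply(pieces, function(w) {
    s <- stats::sd(w)
    if (!is.finite(s) || s == 0)
      return(list(value = NA_real_, undefined = TRUE,
                  reason = "zero-variance window with r specified as a multiple of sigma"))
    sample_entropy(w, m = m, r = r_factor * s, variant = variant)
  })
  vals <- vapply(res, function(z) z$value, 0)
  undef <- vapply(res, function(z) isTRUE(z$undefined), TRUE)
  ok <- vals[!undef]
  structure(
    list(mean = if (length(ok)) mean(ok) else NA_real_,
         se = se_mean(ok),
         values = vals, n_windows = length(pieces),
         n_undefined = sum(undef),
         window = as.integer(window), m = as.integer(m),
         r_factor = r_factor, variant = variant),
    class = "sampen_windowed")
}

#' @export
print.sampen_windowed <- function(x, ...) {
  cat(sprintf(
    "<sampen_windowed> mean = %.4f +/- %s over %d window(s) of %d (m = %d, r = %.2f sigma)\n",
    x$mean, ifelse(is.na(x$se), "NA", sprintf("%.4f", x$se)),
    x$n_windows, x$window, x$m, x$r_factor))
  if (x$n_undefined > 0)
    cat(sprintf("  %d window(s) undefined\n", x$n_undefined))
  invisible(x)
}
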