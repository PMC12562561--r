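#' Min-max normalization of a signal window
#'
#' Maps a window affinely onto `[0, 1]`, removing the effect of the
#' baseline location and absolute amplitude before decomposition.
#'
#' @param window numeric vector with `max > min`.
#' @return normalized vector with minimum 0 and maximum 1.
#' @export
#' @examples
#' minmax_normalize(c(0, 5, 10))
minmax_normalize <- function(window) {
  x <- as.numeric(window)
  rng <- range(x)
  if (rng[1] == rng[2])
    stop("constant window cannot be min-max normalized", call. = FALSE)
  (x - rng[1]) / (rng[2] - rng[1])
}

# Indices of local maxima and minima. Extrema are detected on strict sign
# changes of the first difference; across equal-value plateaus the last
# nonzero slope is carried forward, which places the extremum at the plateau
# end (deterministic).
find_extrema <- function(x) {
  s <- sign(diff(x))
  pos <- which(s != 0)
  if (length(pos) == 0L) return(list(maxima = integer(0), minima = integer(0)))
  f <- findInterval(seq_along(s), pos)
  s2 <- s
  nz <- f > 0L
  s2[nz] <- s[pos][f[nz]]
  s2[!nz] <- 0
  ds <- diff(s2)
  list(maxima = which(ds < 0) + 1L, minima = which(ds > 0) + 1L)
}

# Cubic-spline envelope through the given extrema, mirror-extending two
# extrema beyond each end to tame boundary swings.
spline_envelope <- function(x, idx, n) {
  k <- length(idx)
  head_i <- idx[seq_len(min(2L, k))]
  tail_i <- idx[seq.int(max(1L, k - 1L), k)]
  xi <- c(2L - rev(head_i), idx, 2L * n - rev(tail_i))
  yi <- c(rev(x[head_i]), x[idx], rev(x[tail_i]))
  o <- order(xi)
  xi <- xi[o]; yi <- yi[o]
  keep <- !duplicated(xi)
  stats::spline(xi[keep], yi[keep], xout = seq_len(n), method = "fmm")$y
}

# One sifting pass state: envelopes, their mean, and the IMF conditions.
sift_imf <- function(x, max_sift, mean_tol) {
  n <- length(x)
  h <- x
  e <- find_extrema(h)
  # one extremum of each kind suffices: mirror extension supplies the
  # boundary knots the envelope spline needs
  if (length(e$maxima) < 1L || length(e$minima) < 1L) return(NULL)
  hard_cap <- 4L * max_sift
  best_h <- h
  best_diff <- Inf
  best_it <- 0L
  for (it in seq_len(hard_cap)) {
    up <- spline_envelope(h, e$maxima, n)
    lo <- spline_envelope(h, e$minima, n)
    m <- (up + lo) / 2
    h <- h - m
    e <- find_extrema(h)
    if (length(e$maxima) < 1L || length(e$minima) < 1L)
      return(list(imf = h, n_sift = it))
    n_ext <- length(e$maxima) + length(e$minima)
    zc_diff <- abs(count_zero_crossings(h) - n_ext)
    amp_rms <- sqrt(mean(((up - lo) / 2)^2))
    mean_ok <- amp_rms == 0 || max(abs(m)) <= mean_tol * amp_rms
    # the zero-crossing/extrema rule is mandatory; the envelope-mean rule is
    # relaxed once the iteration budget is spent
    if (zc_diff <= 1L && (mean_ok || it >= max_sift))
      return(list(imf = h, n_sift = it))
    # sifting can oscillate without ever satisfying both rules at once:
    # remember the iterate closest to the zero-crossing condition
    if (zc_diff < best_diff) {
      best_diff <- zc_diff
      best_h <- h
      best_it <- it
    }
  }
  list(imf = best_h, n_sift = best_it)
}

#' Empirical mode decomposition of a signal window
#'
#' Iteratively sifts the signal into intrinsic mode functions (IMFs):
#' upper/lower envelopes are cubic splines through the local
#' maxima/minima, the envelope mean is subtracted, and a candidate is
#' accepted as an IMF once (a) its zero-crossing and extrema counts differ
#' by at most one and (b) its local envelope mean is approximately zero
#' (within `mean_tol` times the RMS envelope amplitude, or when the
#' per-IMF sifting budget is exhausted). Extraction stops when the
#' residual has at most one extremum or is monotonic/constant, or at
#' `max_imf` modes. The decomposition is exact by construction:
#' the IMFs and the residual sum back to the input.
#'
#' @param window numeric vector (>= 8 samples).
#' @param max_imf maximum number of IMFs (default 12).
#' @param max_sift per-IMF sifting budget (default 50).
#' @param mean_tol envelope-mean tolerance relative to the RMS envelope
#'   amplitude (default 0.05).
#' @return an `emd_decomposition`: list with `imfs` (list of numeric
#'   vectors, highest frequency first), `residual`, `n_sift` (iterations
#'   per IMF).
#' @export
#' @examples
#' t <- seq(0, 1, length.out = 1000)
#' d <- emd_decompose(sin(2 * pi * 5 * t) + 0.2 * t)
#' length(d$imfs)
emd_decompose <- function(window, max_imf = 12L, max_sift = 50L,
                          mean_tol = 0.05) {
  x <- as.numeric(window)
  if (length(x) < 8L) stop("window too short for EMD (need >= 8 samples)",
                           call. = FALSE)
  imfs <- list()
  n_sift <- integer(0)
  r <- x
  for (k in seq_len(max_imf)) {
    e <- find_extrema(r)
    if (length(e$maxima) + length(e$minima) <= 1L) break  # residual rule
    s <- sift_imf(r, max_sift = max_sift, mean_tol = mean_tol)
    if (is.null(s)) break
    imfs[[k]] <- s$imf
    n_sift[k] <- s$n_sift
    r <- r - s$imf
  }
  structure(list(imfs = imfs, residual = r, n_sift = n_sift,
                 n = length(x)),
            class = "emd_decomposition")
}

#' @export
print.emd_decomposition <- function(x, ...) {
  cat(sprintf("<emd_decomposition> %d IMF(s) + residual over %d samples\n",
              length(x$imfs), x$n))
  invisible(x)
}

#' Mean-square energy of an IMF
#'
#' The sum of squared IMF values rescaled by the window length, i.e. the
#' mean square. On a min-max normalized window every IMF energy lies in
#' `[0, 1]` and measures the relative contribution of that mode to the
#' signal power per sampling interval.
#'
#' @param imf numeric IMF vector.
#' @return energy (dimensionless).
#' @export
imf_energy <- function(imf) {
  mean(as.numeric(imf)^2)
}

#' Characteristic frequency of an IMF
#'
#' Default estimator: zero-crossing rate, `crossings / (2 * duration)` —
#' cheap, deterministic, and exact for a sinusoid. The alternative
#' `"instantaneous"` estimator averages the analytic-signal instantaneous
#' frequency (FFT-based Hilbert transform).
#'
#' @param imf numeric IMF vector (mean is removed before counting).
#' @param sampling_rate Hz.
#' @param method `"zero_crossing"` (default) or `"instantaneous"`.
#' @return frequency in Hz (0 for an IMF with no crossings).
#' @export
imf_frequency <- function(imf, sampling_rate,
                          method = c("zero_crossing", "instantaneous")) {
  method <- match.arg(method)
  x <- as.numeric(imf)
  if (length(x) < 2L) stop("IMF too short", call. = FALSE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  x <- x - mean(x)
  if (method == "zero_crossing") {
    count_zero_crossings(x) / (2 * length(x) / sampling_rate)
  } else {
    n <- length(x)
    ft <- stats::fft(x)
    h <- numeric(n)
    if (n %% 2L == 0L) {
      h[c(1L, n / 2L + 1L)] <- 1
      h[2L:(n / 2L)] <- 2
    } else {
      h[1L] <- 1
      h[2L:((n + 1L) / 2L)] <- 2
    }
    z <- stats::fft(ft * h, inverse = TRUE) / n
    ph <- Arg(z)
    dph <- diff(ph)
    dph <- (dph + pi) %% (2 * pi) - pi     # unwrap increments
    mean(dph) * sampling_rate / (2 * pi)
  }
}

#' Decompose a trace into windows and extract IMF features
#'
#' Splits a trace into non-overlapping windows of `window` samples
#' (trailing partial windows are dropped and counted), min-max normalizes
#' each, runs [emd_decompose()], and emits one (frequency, energy) feature
#' per IMF. The residual is excluded (it is the trend, not an oscillatory
#' mode).
#'
#' @param trace a [current_trace()].
#' @param window window length in samples (default 100000, i.e. 10 s at
#'   10 kHz).
#' @param ... passed to [emd_decompose()].
#' @return an `imf_features` data frame: `trace_id`, `que_um`, `ca_um`,
#'   `window_idx`, `imf_idx`, `frequency_hz`, `energy`; attribute
#'   `n_dropped_samples` counts the unused tail.
#' @export
decompose_trace_windows <- function(trace, window = 100000L, ...) {
  stopifnot(inherits(trace, "current_trace"))
  check_scalar(window, "window", positive = TRUE)
  window <- as.integer(window)
  x <- trace$samples
  n_win <- length(x) %/% window
  if (n_win == 0L)
    stop(sprintf("trace (%d samples) shorter than one window (%d)",
                 length(x), window), call. = FALSE)
  rows <- list()
  for (w in seq_len(n_win)) {
    seg <- x[((w - 1L) * window + 1L):(w * window)]
    if (min(seg) == max(seg)) next               # constant window: no modes
    d <- emd_decompose(minmax_normalize(seg), ...)
    if (length(d$imfs) == 0L) next
    rows[[length(rows) + 1L]] <- data.frame(
      trace_id = trace$trace_id,
      que_um = trace$que_um, ca_um = trace$ca_um,
      window_idx = w,
      imf_idx = seq_along(d$imfs),
      frequency_hz = vapply(d$imfs, imf_frequency, 0,
                            sampling_rate = trace$sampling_rate),
      energy = vapply(d$imfs, imf_energy, 0),
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(trace_id = character(0), que_um = numeric(0),
               ca_um = numeric(0), window_idx = integer(0),
               imf_idx = integer(0), frequency_hz = numeric(0),
               energy = numeric(0))
  attr(out, "n_dropped_samples") <- length(x) - n_win * window
  class(out) <- c("imf_features", "data.frame")
  out
}
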