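#' Averaged periodogram power spectral density
#'
#' One-sided periodogram averaged over non-overlapping segments of
#' `segment_length` samples, which puts recordings of different lengths on
#' one common frequency grid. Density scaling is Parseval-consistent:
#' `sum(P(f)) * df` equals the mean square of the signal (the variance for
#' zero-mean input). The DC bin is kept, so a constant signal has all its
#' power at `f = 0`.
#'
#' @param trace a [current_trace()] or numeric vector.
#' @param segment_length segment length in samples (default `2^14`).
#' @param sampling_rate required when `trace` is a bare vector.
#' @return a `power_spectrum`: list with `frequency` (Hz), `power`
#'   (pA^2/Hz), `segment_length`, `n_segments`, `sampling_rate`, and an
#'   `estimator` tag.
#' @export
periodogram_psd <- function(trace, segment_length = 2^14,
                            sampling_rate = NULL) {
  if (inherits(trace, "current_trace")) {
    x <- trace$samples
    fs <- trace$sampling_rate
  } else {
    x <- as.numeric(trace)
    if (is.null(sampling_rate))
      stop("`sampling_rate` required for a bare numeric vector", call. = FALSE)
    fs <- sampling_rate
  }
  check_scalar(segment_length, "segment_length", positive = TRUE)
  L <- as.integer(segment_length)
  n_seg <- length(x) %/% L
  if (n_seg < 1L)
    stop(sprintf("trace (%d samples) shorter than one segment (%d)",
                 length(x), L), call. = FALSE)
  seg <- matrix(x[seq_len(n_seg * L)], nrow = L)
  ft <- stats::mvfft(seg)
  n_keep <- L %/% 2L + 1L
  p2 <- Mod(ft[seq_len(n_keep), , drop = FALSE])^2 / (fs * L)
  # one-sided: double everything except DC (and Nyquist when L is even)
  dbl <- rep(2, n_keep)
  dbl[1L] <- 1
  if (L %% 2L == 0L) dbl[n_keep] <- 1
  pw <- rowMeans(p2) * dbl
  structure(
    list(frequency = (seq_len(n_keep) - 1) * fs / L, power = pw,
         segment_length = L, n_segments = n_seg, sampling_rate = fs,
         estimator = "averaged-periodogram"),
    class = "power_spectrum")
}

#' @export
print.power_spectrum <- function(x, ...) {
  cat(sprintf("<power_spectrum> %d bins, 0-%g Hz, %s (%d segment(s) of %d)\n",
              length(x$frequency), max(x$frequency), x$estimator,
              x$n_segments, x$segment_length))
  invisible(x)
}

check_same_grid <- function(spectra) {
  f0 <- spectra[[1]]$frequency
  for (s in spectra[-1]) {
    if (length(s$frequency) != length(f0) ||
        any(abs(s$frequency - f0) > 1e-9))
      stop("spectra are not on a common frequency grid", call. = FALSE)
  }
  f0
}

#' Per-frequency median across power spectra
#'
#' The robust per-condition summary: the median of the spectra of all
#' recordings at one condition, bin by bin.
#'
#' @param spectra list of [periodogram_psd()] results on one grid.
#' @return a `power_spectrum` tagged `median-across-recordings`.
#' @export
median_psd <- function(spectra) {
  stopifnot(is.list(spectra), length(spectra) >= 1L,
            all(vapply(spectra, inherits, TRUE, "power_spectrum")))
  f0 <- check_same_grid(spectra)
  pw <- apply(vapply(spectra, `[[`, numeric(length(f0)), "power"), 1L,
              stats::median)
  out <- spectra[[1]]
  out$power <- pw
  out$n_segments <- sum(vapply(spectra, `[[`, 0L, "n_segments"))
  out$estimator <- "median-across-recordings"
  out
}

#' Control-relative power spectrum
#'
#' The per-frequency ratio of a condition's spectrum to the unstimulated
#' control spectrum: the factor by which each spectral component grows or
#' shrinks under stimulation. Bins where the control power is zero are
#' masked to `NA`.
#'
#' @param condition,control [periodogram_psd()]/[median_psd()] results on
#'   the same grid.
#' @return a `relative_power_spectrum`: list with `frequency`, `ratio`,
#'   `n_masked`.
#' @export
relative_psd <- function(condition, control) {
  stopifnot(inherits(condition, "power_spectrum"),
            inherits(control, "power_spectrum"))
  check_same_grid(list(condition, control))
  ratio <- condition$power / control$power
  masked <- !is.finite(ratio)
  ratio[masked] <- NA_real_
  structure(
    list(frequency = condition$frequency, ratio = ratio,
         n_masked = sum(masked)),
    class = "relative_power_spectrum")
}

# Hamming taper with coefficient a0 over i = 0..W-1.
hamming_taper <- function(W, a0 = 25 / 46) {
  i <- seq_len(W) - 1
  a0 - (1 - a0) * cos(2 * pi * i / W)
}

#' Short-window tapered power spectra of a condition's traces
#'
#' Slides a Hamming-tapered window of `W` samples over each trace and
#' stores the magnitude-squared one-sided FFT of every window. The window
#' defaults to 12.8 ms at the trace sampling rate (128 samples at 10 kHz).
#' By default each recording is processed separately and the windows are
#' pooled, so no window spans a recording boundary; `literal_concat = TRUE`
#' concatenates the traces first. Absolute spectral scaling is irrelevant
#' downstream ([peak_entropy()] bins relative to the pooled SD), so none is
#' applied.
#'
#' @param traces a [current_trace()] or list of them (one condition).
#' @param W window width in samples; default `round(0.0128 * sampling_rate)`.
#' @param stride window advance in samples; default `W/2`. `stride = 1`
#'   enumerates every window.
#' @param a0 Hamming coefficient (default 25/46).
#' @param literal_concat concatenate recordings before windowing?
#' @return a `windowed_spectra`: list with `power` (matrix, frequency bins x
#'   windows), `frequency` (Hz), `W`, `stride`, `a0`, `n_windows`.
#' @export
windowed_spectra <- function(traces, W = NULL, stride = NULL, a0 = 25 / 46,
                             literal_concat = FALSE) {
  if (inherits(traces, "current_trace")) traces <- list(traces)
  stopifnot(length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "current_trace")))
  fs <- traces[[1]]$sampling_rate
  if (any(vapply(traces, `[[`, 0, "sampling_rate") != fs))
    stop("all traces must share one sampling rate", call. = FALSE)
  if (is.null(W)) W <- round(0.0128 * fs)
  W <- as.integer(W)
  if (W < 4L) stop("`W` must be at least 4 samples", call. = FALSE)
  if (is.null(stride)) stride <- max(1L, W %/% 2L)
  stride <- as.integer(stride)
  if (stride < 1L) stop("`stride` must be >= 1", call. = FALSE)

  xs <- if (literal_concat)
    list(unlist(lapply(traces, `[[`, "samples")))
  else
    lapply(traces, `[[`, "samples")
  if (any(vapply(xs, length, 0L) < W))
    stop("window length W exceeds the shortest trace", call. = FALSE)

  taper <- hamming_taper(W, a0)
  n_keep <- W %/% 2L + 1L
  mats <- lapply(xs, function(x) {
    starts <- seq.int(1L, length(x) - W + 1L, by = stride)
    win <- vapply(starts, function(s) x[s:(s + W - 1L)], numeric(W))
    Mod(stats::mvfft(win * taper)[seq_len(n_keep), , drop = FALSE])^2
  })
  pw <- do.call(cbind, mats)
  structure(
    list(power = pw, frequency = (seq_len(n_keep) - 1) * fs / W,
         W = W, stride = stride, a0 = a0, n_windows = ncol(pw),
         sampling_rate = fs),
    class = "windowed_spectra")
}

#' Per-frequency entropy of spectral peak variability
#'
#' Quantifies, for every frequency bin, how variable that spectral
#' component is across time windows. The window spectra of all conditions
#' are pooled to one global mean and SD `sigma_P` (so one set of histogram
#' intervals characterizes all samples); per condition and per frequency
#' the window powers are histogrammed over `(0, 10 sigma_P]` in `K` equal
#' bins and the Shannon entropy (bits) of the within-histogram normalized
#' distribution is reported. Values outside the range are dropped (not
#' clipped) and the dropped fraction recorded. `pooling = "per_frequency"`
#' computes a separate mean/SD per frequency bin instead.
#'
#' @param all_conditions named list of [windowed_spectra()], one per
#'   condition (>= 2 windows each).
#' @param K number of histogram bins (default 1000).
#' @param pooling `"global"` (one mean/SD over everything) or
#'   `"per_frequency"`.
#' @return named list of `peak_entropy_result` objects: `entropy_bits`
#'   (one value per frequency), `frequency`, `dropped_fraction`, plus the
#'   pooled `mean` and `sd` and `K`.
#' @export
peak_entropy <- function(all_conditions, K = 1000L,
                         pooling = c("global", "per_frequency")) {
  pooling <- match.arg(pooling)
  if (inherits(all_conditions, "windowed_spectra"))
    all_conditions <- list(condition = all_conditions)
  stopifnot(length(all_conditions) >= 1L,
            all(vapply(all_conditions, inherits, TRUE, "windowed_spectra")))
  if (any(vapply(all_conditions, function(w) ncol(w$power), 0L) < 2L))
    stop("each condition needs at least 2 windows", call. = FALSE)
  f0 <- check_same_grid(all_conditions)
  K <- as.integer(K)

  all_pw <- lapply(all_conditions, `[[`, "power")
  if (pooling == "global") {
    pooled <- unlist(all_pw, use.names = FALSE)
    p_mean <- mean(pooled)
    p_sd <- stats::sd(pooled)
  } else {
    stacked <- do.call(cbind, all_pw)
    p_mean <- rowMeans(stacked)
    p_sd <- apply(stacked, 1L, stats::sd)
  }
  if (any(p_sd == 0))
    stop("degenerate spectra: pooled SD is zero", call. = FALSE)

  lapply(all_conditions, function(ws) {
    pw <- ws$power
    nf <- nrow(pw)
    H <- numeric(nf)
    dropped <- numeric(nf)
    for (i in seq_len(nf)) {
      s <- if (pooling == "global") p_sd else p_sd[i]
      v <- pw[i, ]
      inr <- v > 0 & v <= 10 * s
      dropped[i] <- 1 - mean(inr)
      v <- v[inr]
      if (length(v) == 0L) { H[i] <- 0; next }
      idx <- pmin(ceiling(v / (10 * s / K)), K)  # bin k covers ((k-1)w, kw]
      cnt <- tabulate(idx, nbins = K)
      H[i] <- shannon_entropy(cnt / sum(cnt))
    }
    structure(
      list(entropy_bits = H, frequency = f0, dropped_fraction = dropped,
           mean = p_mean, sd = p_sd, K = K, pooling = pooling),
      class = "peak_entropy_result")
  })
}
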