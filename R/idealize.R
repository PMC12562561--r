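#' Estimate closed and open conductance levels from a trace
#'
#' Locates the two dominant modes of the kernel-smoothed all-points
#' amplitude histogram. Peaks are ranked by topographic prominence (height
#' above the deepest saddle separating them from a taller peak), which is
#' robust against shoulders of a dominant conductance level when one class
#' holds most of the samples. The two most prominent modes must also be
#' separated by at least `min_separation_sd` times the estimated baseline
#' noise SD (from the median absolute first difference); otherwise an
#' error asks the caller to supply the levels explicitly to
#' [half_amplitude_idealize()].
#'
#' @param trace a [current_trace()].
#' @param min_separation_sd minimum mode separation in noise SDs.
#' @return named numeric `c(closed_level, open_level)`; the level farther
#'   from zero (larger absolute current) is reported as the open level.
#' @export
estimate_levels <- function(trace, min_separation_sd = 4) {
  stopifnot(inherits(trace, "current_trace"))
  x <- trace$samples
  noise_sd <- stats::mad(diff(x)) / sqrt(2)
  if (noise_sd == 0) noise_sd <- stats::sd(x) / 100
  d <- stats::density(x, n = 1024)
  y <- d$y
  loc_max <- which(diff(sign(diff(y))) < 0) + 1L
  if (length(loc_max) < 2L || noise_sd == 0)
    stop("amplitude histogram is not bimodal; supply closed/open levels ",
         "explicitly", call. = FALSE)
  prominence <- vapply(loc_max, function(p) {
    higher <- loc_max[y[loc_max] > y[p]]
    if (length(higher) == 0L) return(y[p] - min(y))
    saddle <- -Inf
    left <- higher[higher < p]
    if (length(left)) saddle <- max(saddle, min(y[max(left):p]))
    right <- higher[higher > p]
    if (length(right)) saddle <- max(saddle, min(y[p:min(right)]))
    if (!is.finite(saddle)) saddle <- min(y)
    y[p] - saddle
  }, 0)
  ord <- loc_max[order(prominence, decreasing = TRUE)]
  first <- ord[1L]
  second <- ord[2L]
  if (abs(d$x[second] - d$x[first]) < min_separation_sd * noise_sd)
    stop("amplitude histogram is not bimodal; supply closed/open levels ",
         "explicitly", call. = FALSE)
  lv <- sort(c(d$x[first], d$x[second]))
  # open = larger magnitude relative to baseline zero (handles negative-going
  # openings through ordering, not absolute sign)
  if (abs(lv[2]) >= abs(lv[1])) {
    c(closed_level = lv[1], open_level = lv[2])
  } else {
    c(closed_level = lv[2], open_level = lv[1])
  }
}

#' Idealize a trace with the half-amplitude threshold
#'
#' Classifies every sample as open or closed using the threshold midway
#' between the two conductance levels. A sample is open iff it lies
#' strictly on the open side of the threshold; a sample exactly at the
#' threshold is classified closed (conservative, deterministic tie rule).
#' Works for positive- or negative-going openings.
#'
#' @param trace a [current_trace()].
#' @param closed_level,open_level conductance levels in pA; estimated with
#'   [estimate_levels()] when omitted.
#' @return an `idealized_trace`: logical vector `open` plus the threshold,
#'   levels, sampling rate and trace metadata.
#' @export
#' @examples
#' tr <- current_trace(c(1, 6, 9, 4), 10000)
#' half_amplitude_idealize(tr, 0, 10)$open
half_amplitude_idealize <- function(trace, closed_level = NULL,
                                    open_level = NULL) {
  stopifnot(inherits(trace, "current_trace"))
  if (is.null(closed_level) || is.null(open_level)) {
    lv <- estimate_levels(trace)
    closed_level <- lv[["closed_level"]]
    open_level <- lv[["open_level"]]
  }
  if (closed_level == open_level)
    stop("closed and open levels must differ", call. = FALSE)
  threshold <- (closed_level + open_level) / 2
  open <- if (open_level > closed_level)
    trace$samples > threshold
  else
    trace$samples < threshold
  structure(
    list(open = open, threshold = threshold,
         closed_level = closed_level, open_level = open_level,
         sampling_rate = trace$sampling_rate,
         trace_id = trace$trace_id, que_um = trace$que_um,
         ca_um = trace$ca_um),
    class = "idealized_trace")
}

#' @export
print.idealized_trace <- function(x, ...) {
  cat(sprintf(
    "<idealized_trace> '%s': %d samples, threshold %.3g pA, p_op = %.3f\n",
    x$trace_id, length(x$open), x$threshold, mean(x$open)))
  invisible(x)
}

#' Extract the dwell-time series from an idealized trace
#'
#' Run-length encodes the open/closed state sequence; each dwell duration
#' is the run length times the sampling interval, so durations are positive
#' integer multiples of `1/sampling_rate` and sum exactly to the trace
#' duration. One-sample events are retained (no missed-event correction).
#'
#' @param ideal an [half_amplitude_idealize()] result.
#' @param sampling_rate sampling rate in Hz; defaults to the one stored in
#'   `ideal`.
#' @return a `dwell_times` data frame with columns `state` (`"O"`/`"C"`) and
#'   `duration` (s), carrying the trace metadata as attributes.
#' @export
extract_dwell_times <- function(ideal, sampling_rate = ideal$sampling_rate) {
  stopifnot(inherits(ideal, "idealized_trace"))
  if (length(ideal$open) == 0L) stop("empty state sequence", call. = FALSE)
  r <- rle(ideal$open)
  out <- data.frame(state = ifelse(r$values, "O", "C"),
                    duration = r$lengths / sampling_rate,
                    stringsAsFactors = FALSE)
  attr(out, "trace_id") <- ideal$trace_id
  attr(out, "que_um") <- ideal$que_um
  attr(out, "ca_um") <- ideal$ca_um
  attr(out, "sampling_rate") <- sampling_rate
  class(out) <- c("dwell_times", "data.frame")
  out
}

#' Open-state probability of an idealized trace
#'
#' The fraction of samples assigned to the open state.
#'
#' @param ideal an [half_amplitude_idealize()] result.
#' @return probability in `[0, 1]`.
#' @export
open_probability <- function(ideal) {
  stopifnot(inherits(ideal, "idealized_trace"))
  mean(ideal$open)
}
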