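#' Construct a single-channel current trace
#'
#' A thin container for a sampled current recording: the sample values in
#' pA, the sampling rate, and the condition metadata (activator
#' concentrations) that every downstream table is tagged with.
#'
#' @param samples numeric vector of currents in pA (>= 2 samples).
#' @param sampling_rate sampling rate in Hz.
#' @param que_um,ca_um activator concentrations in uM; `NA` if unknown.
#' @param trace_id identifier carried into all outputs.
#' @param amplifier_error optional amplifier resolution in pA.
#' @param seed optional integer recording the seed a synthetic trace was
#'   generated from.
#' @return a `current_trace` object.
#' @export
current_trace <- function(samples, sampling_rate, que_um = NA_real_,
                          ca_um = NA_real_, trace_id = "trace",
                          amplifier_error = NULL, seed = NULL) {
  samples <- as.numeric(samples)
  if (length(samples) < 2L)
    stop("a trace needs at least 2 samples", call. = FALSE)
  if (anyNA(samples)) stop("trace contains NA samples", call. = FALSE)
  check_scalar(sampling_rate, "sampling_rate", positive = TRUE)
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         que_um = que_um, ca_um = ca_um, trace_id = trace_id,
         amplifier_error = amplifier_error, seed = seed),
    class = "current_trace")
}

#' @export
print.current_trace <- function(x, ...) {
  cat(sprintf(
    "<current_trace> '%s': %d samples @ %g Hz (%.3f s), [Que] = %s uM, [Ca] = %s uM\n",
    x$trace_id, length(x$samples), x$sampling_rate,
    length(x$samples) / x$sampling_rate,
    format(x$que_um), format(x$ca_um)))
  invisible(x)
}

#' @export
length.current_trace <- function(x) length(x$samples)

condition_key <- function(trace) {
  sprintf("que%g_ca%g",
          ifelse(is.na(trace$que_um), 0, trace$que_um),
          ifelse(is.na(trace$ca_um), 0, trace$ca_um))
}
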