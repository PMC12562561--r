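#' Write a current trace to disk
#'
#' Two dialects: `"csv"` writes `time_s,current_pA` rows at full double
#' precision (lossless round trip), `"float32"` writes a raw little-endian
#' 32-bit float array. Both formats get a JSON sidecar `<path>.json` with
#' the sampling rate, units, condition and seed, which [read_trace()] uses
#' to restore metadata.
#'
#' @param trace a [current_trace()].
#' @param path output file path.
#' @param format `"csv"` or `"float32"`.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path, format = c("csv", "float32")) {
  format <- match.arg(format)
  stopifnot(inherits(trace, "current_trace"))
  if (format == "csv") {
    n <- length(trace$samples)
    df <- data.frame(
      time_s = sprintf("%.17g", (seq_len(n) - 1) / trace$sampling_rate),
      current_pA = sprintf("%.17g", trace$samples))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(as.numeric(trace$samples), con, size = 4L, endian = "little")
  }
  sidecar <- list(sampling_rate_hz = trace$sampling_rate, units = "pA",
                  que_um = trace$que_um, ca_um = trace$ca_um,
                  trace_id = trace$trace_id, seed = trace$seed,
                  format = format, n_samples = length(trace$samples))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a current trace from disk
#'
#' Reads the CSV or raw-float32 dialect written by [write_trace()]. The
#' JSON sidecar `<path>.json` supplies the sampling rate and condition
#' metadata; without a sidecar, `sampling_rate` must be given explicitly
#' (a CSV alone does not carry it authoritatively) and the float32 dialect
#' cannot be sized-checked.
#'
#' @param path input file path.
#' @param format `"csv"` or `"float32"`; inferred from the sidecar or file
#'   extension when omitted.
#' @param sampling_rate Hz; overrides/replaces the sidecar value.
#' @return a [current_trace()].
#' @export
read_trace <- function(path, format = NULL, sampling_rate = NULL) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  sidecar_path <- paste0(path, ".json")
  meta <- if (file.exists(sidecar_path))
    jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
  else NULL
  if (is.null(format))
    format <- meta$format %||%
      (if (grepl("\\.csv$", path, ignore.case = TRUE)) "csv" else "float32")
  fs <- sampling_rate %||% meta$sampling_rate_hz
  if (is.null(fs))
    stop("sampling rate unavailable: no sidecar and no `sampling_rate` given",
         call. = FALSE)
  if (format == "csv") {
    df <- utils::read.csv(path)
    if (!"current_pA" %in% names(df))
      stop("CSV trace must have a `current_pA` column", call. = FALSE)
    samples <- df$current_pA
  } else {
    sz <- file.info(path)$size
    con <- file(path, "rb")
    on.exit(close(con))
    samples <- readBin(con, what = "numeric", n = sz %/% 4L, size = 4L,
                       endian = "little")
    if (!is.null(meta$n_samples) && length(samples) != meta$n_samples)
      stop("truncated binary trace: expected ", meta$n_samples,
           " samples, read ", length(samples), call. = FALSE)
  }
  if (anyNA(samples)) stop("trace contains NA samples", call. = FALSE)
  null_na <- function(v) if (is.null(v) || length(v) == 0L) NA_real_ else v
  current_trace(samples, fs,
                que_um = null_na(meta$que_um), ca_um = null_na(meta$ca_um),
                trace_id = meta$trace_id %||% basename(path),
                seed = meta$seed)
}

#' Export an event sequence or dwell-time series as CSV
#'
#' Writes `state,duration_s` rows.
#'
#' @param x an `event_sequence` or `dwell_times` data frame.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_dwells <- function(x, path) {
  stopifnot(is.data.frame(x), all(c("state", "duration") %in% names(x)))
  df <- data.frame(state = x$state,
                   duration_s = sprintf("%.17g", x$duration))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
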