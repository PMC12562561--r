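#' Pipeline parameter set
#'
#' Bundles every tunable of the per-condition analysis pipeline with its
#' default. Defaults mirror the package-wide conventions: 10 kHz
#' acquisition, dwell-series SampEn windows of 4000 dwells with
#' `r = 0.2 sigma` and `m = 2`, PSD segments of 2^14 samples, 12.8 ms
#' Hamming windows, K = 1000 peak-entropy bins, EMD windows of 100000
#' samples, six IMF clusters.
#'
#' @param control numeric `c(que_um, ca_um)` identifying the control
#'   condition (default `c(0, 0)`).
#' @param levels optional `c(closed_level, open_level)`; estimated per
#'   trace when `NULL`.
#' @param sampen_window,sampen_m,sampen_r_factor dwell-series SampEn
#'   parameters.
#' @param psd_segment periodogram segment length (samples).
#' @param spectra_W,spectra_stride windowed-spectra parameters (samples);
#'   `NULL` for the 12.8 ms / half-overlap defaults.
#' @param peak_K peak-entropy histogram bins.
#' @param emd_window EMD window length (samples).
#' @param cluster_k number of IMF clusters.
#' @param seed master seed for the stochastic stages.
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(control = c(que_um = 0, ca_um = 0),
                            levels = NULL,
                            sampen_window = 4000L, sampen_m = 2L,
                            sampen_r_factor = 0.2,
                            psd_segment = 2^14,
                            spectra_W = NULL, spectra_stride = NULL,
                            peak_K = 1000L,
                            emd_window = 100000L,
                            cluster_k = 6L,
                            seed = 1L) {
  structure(
    list(control = control, levels = levels,
         sampen_window = sampen_window, sampen_m = sampen_m,
         sampen_r_factor = sampen_r_factor,
         psd_segment = psd_segment,
         spectra_W = spectra_W, spectra_stride = spectra_stride,
         peak_K = peak_K, emd_window = emd_window,
         cluster_k = cluster_k, seed = seed),
    class = "pipeline_config")
}

#' Run the full per-condition analysis pipeline
#'
#' Groups traces by condition (`que_um`, `ca_um`), then per condition:
#' idealizes every trace, computes open probability (mean and SE across
#' traces), pools dwell times into the Shannon-entropy histogram, computes
#' windowed dwell-series SampEn, the median PSD with its control-relative
#' ratio, the windowed spectral peak entropies (global pooled binning over
#' all conditions), and the EMD feature histogram with six-cluster
#' summaries. Stage failures are caught and recorded per condition; the
#' remaining stages still run.
#'
#' @param traces list of [current_trace()] objects covering at least the
#'   control condition.
#' @param config a [pipeline_config()].
#' @param out_dir optional directory; when given, every result table is
#'   written as CSV plus a JSON run manifest, and outputs are
#'   byte-reproducible for a fixed config and seed.
#' @param stages character subset of
#'   `c("idealize", "entropy", "spectral", "emd")` to run; later stages
#'   depend on `"idealize"`.
#' @return a `pipeline_result`: named list of per-condition summaries
#'   (`p_op`, `dwell_entropy_bits`, `dwell_entropy_vs_control`, `sampen`,
#'   `median_psd`, `relative_psd`, `peak_entropy`, `cluster_summaries`,
#'   `errors`), plus `config`.
#' @export
run_pipeline <- function(traces, config = pipeline_config(), out_dir = NULL,
                         stages = c("idealize", "entropy", "spectral", "emd")) {
  stopifnot(is.list(traces), length(traces) >= 1L,
            all(vapply(traces, inherits, TRUE, "current_trace")),
            inherits(config, "pipeline_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  keys <- vapply(traces, condition_key, "")
  control_key <- sprintf("que%g_ca%g", config$control[1], config$control[2])
  if (!control_key %in% keys)
    stop("control condition ", control_key, " not present in the traces",
         call. = FALSE)
  groups <- split(traces, keys)
  # control first so relative quantities can be formed in one pass
  groups <- groups[c(control_key, setdiff(names(groups), control_key))]

  res <- lapply(groups, function(g) {
    out <- list(n_traces = length(g),
                que_um = g[[1]]$que_um, ca_um = g[[1]]$ca_um,
                errors = character(0))
    grab <- function(stage, expr) {
      tryCatch(expr, error = function(e) {
        out$errors[stage] <<- conditionMessage(e)
        NULL
      })
    }
    ideals <- grab("idealize", lapply(g, function(tr) {
      if (is.null(config$levels)) half_amplitude_idealize(tr)
      else half_amplitude_idealize(tr, config$levels[1], config$levels[2])
    }))
    if (!is.null(ideals)) {
      pops <- vapply(ideals, open_probability, 0)
      out$p_op <- mean(pops)
      out$p_op_se <- se_mean(pops)
      out$dwells <- do.call(rbind, lapply(ideals, extract_dwell_times))
      attr(out$dwells, "sampling_rate") <- g[[1]]$sampling_rate
    }
    if ("entropy" %in% stages && !is.null(out$dwells)) {
      out$dwell_entropy_bits <- grab("entropy", {
        h <- dwell_histogram(out$dwells)
        shannon_entropy(h$probabilities)
      })
      out$sampen <- grab("entropy", windowed_sample_entropy(
        out$dwells, window = config$sampen_window, m = config$sampen_m,
        r_factor = config$sampen_r_factor))
    }
    if ("spectral" %in% stages) {
      out$median_psd <- grab("spectral", median_psd(
        lapply(g, periodogram_psd, segment_length = config$psd_segment)))
      out$windowed_spectra <- grab("spectral", windowed_spectra(
        g, W = config$spectra_W, stride = config$spectra_stride))
    }
    if ("emd" %in% stages) {
      out$imf_features <- grab("emd", {
        feats <- do.call(rbind, lapply(g, decompose_trace_windows,
                                       window = config$emd_window))
        class(feats) <- c("imf_features", "data.frame")
        feats
      })
      if (!is.null(out$imf_features) && nrow(out$imf_features) > 0L) {
        out$cluster_summaries <- grab("emd", {
          h <- feature_histogram_2d(out$imf_features)
          cl <- cluster_features(h, k = config$cluster_k, seed = config$seed)
          cluster_summaries(cl)
        })
      }
    }
    out
  })

  # cross-condition stages: relative PSD, entropy rescaling, peak entropy
  ctrl <- res[[control_key]]
  for (key in names(res)) {
    if (!is.null(res[[key]]$median_psd) && !is.null(ctrl$median_psd))
      res[[key]]$relative_psd <- relative_psd(res[[key]]$median_psd,
                                              ctrl$median_psd)
    if (!is.null(res[[key]]$dwell_entropy_bits) &&
        !is.null(ctrl$dwell_entropy_bits) && ctrl$dwell_entropy_bits > 0)
      res[[key]]$dwell_entropy_vs_control <-
        res[[key]]$dwell_entropy_bits / ctrl$dwell_entropy_bits
  }
  ws_all <- lapply(res, `[[`, "windowed_spectra")
  ws_all <- ws_all[!vapply(ws_all, is.null, TRUE)]
  if (length(ws_all)) {
    pe <- tryCatch(peak_entropy(ws_all, K = config$peak_K),
                   error = function(e) NULL)
    if (!is.null(pe)) for (key in names(pe)) res[[key]]$peak_entropy <- pe[[key]]
  }
  for (key in names(res)) res[[key]]$windowed_spectra <- NULL  # bulky

  result <- structure(list(conditions = res, config = config,
                           control = control_key),
                      class = "pipeline_result")
  if (!is.null(out_dir)) write_pipeline_outputs(result, out_dir)
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d condition(s), control = %s\n",
              length(x$conditions), x$control))
  for (key in names(x$conditions)) {
    c_ <- x$conditions[[key]]
    cat(sprintf("  %-14s n = %d, p_op = %s, H(dwell) = %s bits, SampEn = %s\n",
                key, c_$n_traces,
                if (is.null(c_$p_op)) "-" else sprintf("%.3f", c_$p_op),
                if (is.null(c_$dwell_entropy_bits)) "-" else
                  sprintf("%.3f", c_$dwell_entropy_bits),
                if (is.null(c_$sampen)) "-" else sprintf("%.3f", c_$sampen$mean)))
    if (length(c_$errors))
      cat("    stage errors:", paste(names(c_$errors), collapse = ", "), "\n")
  }
  invisible(x)
}

# Write every table of a pipeline_result as CSV plus a JSON run manifest.
write_pipeline_outputs <- function(result, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  rows <- list(); pe_rows <- list(); cl_rows <- list(); psd_rows <- list()
  for (key in names(result$conditions)) {
    c_ <- result$conditions[[key]]
    add <- function(metric, value, se = NA_real_, n = NA_integer_) {
      rows[[length(rows) + 1L]] <<- data.frame(
        condition = key, que_um = c_$que_um, ca_um = c_$ca_um,
        metric = metric, value = value, se = se, n_windows = n)
    }
    if (!is.null(c_$p_op)) add("p_op", c_$p_op, c_$p_op_se %||% NA_real_,
                               c_$n_traces)
    if (!is.null(c_$dwell_entropy_bits))
      add("dwell_shannon_bits", c_$dwell_entropy_bits)
    if (!is.null(c_$dwell_entropy_vs_control))
      add("dwell_shannon_vs_control", c_$dwell_entropy_vs_control)
    if (!is.null(c_$sampen))
      add("sampen", c_$sampen$mean, c_$sampen$se %||% NA_real_,
          c_$sampen$n_windows)
    if (!is.null(c_$median_psd))
      psd_rows[[length(psd_rows) + 1L]] <- data.frame(
        condition = key, frequency_hz = c_$median_psd$frequency,
        power = c_$median_psd$power,
        relative = if (is.null(c_$relative_psd)) NA_real_ else
          c_$relative_psd$ratio)
    if (!is.null(c_$peak_entropy))
      pe_rows[[length(pe_rows) + 1L]] <- data.frame(
        condition = key, frequency_hz = c_$peak_entropy$frequency,
        entropy_bits = c_$peak_entropy$entropy_bits)
    if (!is.null(c_$cluster_summaries))
      cl_rows[[length(cl_rows) + 1L]] <- cbind(
        data.frame(condition = key, que_um = c_$que_um, ca_um = c_$ca_um),
        c_$cluster_summaries)
  }
  wr <- function(lst, name) if (length(lst))
    utils::write.csv(do.call(rbind, lst), file.path(out_dir, name),
                     row.names = FALSE)
  wr(rows, "summary_metrics.csv")
  wr(psd_rows, "psd.csv")
  wr(pe_rows, "peak_entropy.csv")
  wr(cl_rows, "cluster_summaries.csv")
  manifest <- list(
    package_version = as.character(utils::packageVersion("scgating")),
    seed = result$config$seed,
    control = result$control,
    conditions = names(result$conditions),
    config = result$config[setdiff(names(result$config), "levels")],
    errors = lapply(result$conditions, `[[`, "errors"))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(out_dir)
}
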