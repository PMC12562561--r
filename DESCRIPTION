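Package: scgating
Title: Entropic, Spectral, and Mode-Decomposition Analysis of
    Single-Channel Patch-Clamp Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for quantifying single-channel patch-clamp recordings of
    ion channels such as the large-conductance calcium- and voltage-activated
    potassium (BK) channel. Provides half-amplitude idealization of current
    traces into open/closed state sequences, open-state probability and
    dwell-time extraction, Shannon entropy of dwell-time distributions,
    windowed sample entropy of dwell-time series, averaged and median power
    spectral densities with relative (control-normalized) spectra, windowed
    Hamming-tapered spectra with per-frequency peak-variability entropy,
    empirical mode decomposition of normalized signal windows with
    frequency-energy feature extraction, and weighted k-means clustering of
    intrinsic mode function populations. A semi-Markov gating simulator with
    exponential and truncated-Pareto dwell distributions generates synthetic
    recordings with analytic ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
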