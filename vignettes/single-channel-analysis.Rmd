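---
title: "Quantifying single-channel gating: entropies, spectra, and mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying single-channel gating: entropies, spectra, and mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(scgating)
```

## The problem

A single-channel patch-clamp recording is a noisy two-level time series:
the current through one ion-channel protein switches between a
non-conducting (closed) and a conducting (open) level as the protein
changes conformation. Classical summaries — the open-state probability
`p_op` and the dwell-time distributions of open and closed episodes —
compress the recording heavily, and distinct gating mechanisms can produce
nearly identical `p_op`. This package implements a set of complementary
descriptors that are sensitive to *how* the channel switches, not just how
often it is open:

* Shannon entropy of the pooled dwell-time histogram — how many distinct
  timescales take part in gating;
* sample entropy (SampEn) of the dwell-time series — how predictable the
  sequence of dwell durations is;
* median and control-relative power spectral densities — where in the
  frequency domain stimulation changes the signal;
* per-frequency entropy of short-window spectral peaks — how variable each
  spectral component is over time;
* empirical mode decomposition (EMD) of normalized signal windows, with the
  population of intrinsic mode functions (IMFs) summarized as a clustered
  frequency–energy histogram.

Because real recordings of this kind are rarely deposited, the package
ships a semi-Markov gating simulator that generates synthetic recordings
with known ground truth; every estimator in the package is validated
against it.

## The gating model

`gating_model()` describes a channel as an alternating semi-Markov chain: a
set of open and closed states, each with its own dwell-time distribution,
and a transition matrix of the embedded jump chain that must move between
conducting classes at every step (open and closed episodes strictly
alternate in the recording; consecutive same-class states are
indistinguishable at the current level and are folded into the dwell
distributions instead).

Dwell distributions are either exponential with mean `tau`, or a power law
with density `f(t) ~ t^(-alpha)` on `[t_min, t_max]`. Under this
convention the log–log survival curve of dwell times has slope
`-(alpha - 1)`, the quantity a scientist reads off a survival plot; `alpha`
must exceed 1 for normalizability and the upper cap keeps the mean finite
(an uncapped power law with `alpha <= 2` has infinite mean and
`state_mean_dwell()` reports `Inf`).

`stationary_open_probability()` gives the exact long-run open fraction
(`sum over open states of pi_i * E[dwell_i]` over the same sum for all
states, with `pi` the stationary distribution of the embedded chain); it is
the analytic oracle the idealization chain is tested against.

Rendering (`render_current_trace()`) follows typical acquisition settings:
two conductance levels, i.i.d. Gaussian noise, a 4-pole Bessel-type
low-pass at 1 kHz, and 10 kHz digitization. Event boundaries are quantized
to the sample grid by sample-midpoint occupancy, which makes the mapping
from exact events to samples deterministic and testable. All randomness
derives from one seed through named streams (events vs noise), so gating
can be held fixed while the noise realization varies.

### The shipped regimes

The shipped study design contrasts an unstimulated control with chemically
activated conditions. No rate constants are available for the underlying
recordings, so the three `gating_regime()` presets are package choices,
calibrated once to reproduce the qualitative signatures reported for this
channel type, as measured through the package's own analysis chain
(render, then idealize — not only on exact simulated events, because
1 kHz filtering and half-amplitude thresholding reshape brief events):

* `control` — 2 open (1, 9 ms) + 3 closed (0.5, 6, 80 ms) exponential
  states: several well-separated timescales, `p_op` about 0.18, a broad
  dwell histogram.
* `ca_high` — strong activation: long openings (3, 12 ms, weighted toward
  the longer state) and power-law closed dwells (`alpha = 1.5`,
  `t_min = 0.1 ms`, caps 1–5 ms), giving `p_op` about 0.95 and a measured
  dwell entropy 0.15–0.18 bits below control across independent seed sets
  — the "stabilized long openings, short closings" signature.
* `que_low` — weak activation: near-control `p_op` (about 0.16) with more
  evenly mixed intermediate timescales. We make no ordering claim for its
  measured dwell entropy relative to control; it exists to provide a
  condition whose kinetics change while `p_op` does not.

## Idealization

`half_amplitude_idealize()` applies the standard half-amplitude threshold:
a sample is open iff it lies strictly on the open side of the midpoint
between the two conductance levels; a sample exactly at the threshold is
closed (a deterministic, conservative tie rule). The level pair either
comes from the caller or from `estimate_levels()`, which ranks the modes
of a kernel-smoothed all-points amplitude histogram by topographic
prominence. Prominence (height above the deepest saddle toward a taller
peak) rather than raw height is essential when one conductance class holds
95% of the samples: the minority-level peak is small but prominent, while
shoulders of the majority peak are tall but not prominent. Two modes must
additionally be separated by at least 4 estimated noise SDs; otherwise the
function refuses and asks for explicit levels.

`extract_dwell_times()` run-length encodes the state sequence, so dwell
durations are positive multiples of the sampling interval and sum exactly
to the trace duration. One-sample events are retained: no missed-event
(filter dead-time) correction is applied, which is a known limitation —
measured dwell statistics are those of the *filtered, thresholded* signal,
and brief events below the filter rise time are systematically merged into
their neighbours.

## Entropies

`dwell_histogram()` pools open and closed durations into log-spaced bins
(8 per decade from the sampling interval to 100 s by default, shared
across conditions so entropies are comparable) and `shannon_entropy()`
reports `-sum(p log2 p)` in bits. Pooling open with closed dwells is a
package choice; the histogram object also accepts a `states` filter for
separate analyses.

`sample_entropy()` implements SampEn with Chebyshev distance: the negative
natural log of the conditional probability that subsequences similar for
`m` points stay similar at point `m + 1`. Defaults are `m = 2` and
`r = 0.2` times the series SD, the customary settings for dwell-time
series of channel recordings. Two normalizations are provided: the default
counts matches over all `N - m + 1` length-`m` templates with denominator
`N - m`; `variant = "richman"` is the canonical Richman–Moorman form
restricted to the `N - m` templates that extend. The two differ only by
boundary templates (for a strictly periodic series the canonical form is
exactly 0 while the default carries a boundary term below 1e-3) and
converge as `N` grows. When no `(m+1)`-match exists the result is flagged
undefined rather than returned as infinity. The compiled counting core is
validated against an independent full-distance-matrix oracle to 1e-12 in
the test suite.

`windowed_sample_entropy()` follows the windowing convention for dwell
series: non-overlapping windows of 4000 dwells, `r` rescaled to each
window's SD, mean and standard error across windows. With fewer dwells
than one window it falls back to a single window with a warning — at the
packaged demo scale (3 traces of 20 s per condition) the control condition
produces one to two windows, so per-condition SampEn standard errors are
reported but small-sample.

## Spectral description

`periodogram_psd()` averages one-sided periodograms over non-overlapping
segments (2^14 samples by default), which places recordings of different
lengths on one frequency grid — a prerequisite for the per-frequency
median across recordings (`median_psd()`) and the control-relative ratio
(`relative_psd()`). Scaling is Parseval-consistent: the integral of the
density equals the mean square of the analyzed samples (the variance for
zero-mean signals). The DC bin is kept, so a constant signal shows all its
power at zero frequency; control bins with zero power are masked (NA) in
ratios rather than producing infinities.

`windowed_spectra()` slides a Hamming window (`a0 = 25/46`, width 12.8 ms
= 128 samples at 10 kHz) along each trace and stores the magnitude-squared
one-sided FFT of every window. Two deliberate deviations from the most
literal formulation are defaulted and reversible:

* stride: enumerating every sample-step window is quadratic in practice;
  the default advances by half a window (`stride = W/2`), and `stride = 1`
  restores the exhaustive enumeration;
* recording boundaries: windows never span two recordings by default
  (windows are pooled across recordings afterwards);
  `literal_concat = TRUE` concatenates first.

`peak_entropy()` then asks, per frequency bin: how variable is this
spectral component across time windows? All conditions are pooled into one
global mean and SD (`sigma_P`), window powers are histogrammed over
`(0, 10 sigma_P]` in `K = 1000` equal bins, and the Shannon entropy of the
normalized histogram is reported per frequency. Global pooling (one
binning for all samples) is the default because it keeps conditions
directly comparable; `pooling = "per_frequency"` computes per-frequency
statistics instead, since the choice between the two is genuinely open.
Values outside the range are dropped, not clipped, and the dropped
fraction is reported. No absolute spectral scaling is applied inside the
windows: the binning is relative to `sigma_P`, so any common factor
cancels.

## Empirical mode decomposition

`emd_decompose()` implements sifting with cubic-spline envelopes through
the local extrema (two extrema mirror-extended beyond each end to tame
boundary swings). A candidate is accepted as an IMF when its zero-crossing
and extrema counts differ by at most one and its envelope mean is
approximately zero; tolerances the classical description leaves open are
fixed as: envelope-mean magnitude at most 0.05 times the RMS envelope
amplitude, at most 50 sifting passes per IMF (the envelope-mean condition
is relaxed when that budget is spent — the zero-crossing condition is
not), and at most 12 IMFs per window. Sifting on broadband signals can
oscillate without ever satisfying both conditions simultaneously; in that
case the iterate closest to the zero-crossing condition is kept. Extrema
are detected on strict sign changes of the first difference, with plateaus
resolved deterministically to the plateau end. Decomposition is exact by
construction (IMFs plus residual reproduce the input to machine
precision), and extraction stops when the residual has at most one
extremum or is monotonic — the residual is the signal's trend and is
excluded from all downstream feature populations.

Windows of 100 000 samples (10 s at 10 kHz) are min–max normalized before
decomposition so the baseline position and absolute amplitude do not leak
into IMF energies. Each IMF contributes one feature: its energy (mean
square of the normalized-signal IMF, necessarily in `[0, 1]`) and its
characteristic frequency. The frequency estimator is the zero-crossing
rate by default — cheap, deterministic, exact for sinusoids; a
mean-instantaneous-frequency estimator (FFT-based analytic signal) is
available via `method = "instantaneous"` since the choice of estimator for
an IMF's "frequency" is not canonical.

## Clustering the IMF population

`feature_histogram_2d()` bins the feature population on a shared
log-frequency by log-energy grid (60 by 60 cells over 1 Hz–5 kHz and
1e-8–1 by default). `cluster_features()` runs weighted k-means (weights =
cell counts, k-means++ initialization, best of 20 restarts, fixed seed) on
the occupied cell centers in log–log space — Euclidean distance in linear
units would be dominated by the highest decade. Six clusters is the
default, matching the structure typically visible in such histograms: a
low-frequency low/high-energy pair and four higher-frequency groups.
Cluster labels are canonicalized by ascending centroid frequency then
energy, so cluster indices are comparable across conditions.
`cluster_summaries()` reports, per cluster, the count-weighted centroid
(back-transformed to Hz and linear energy), the occupancy (fraction of all
IMFs), and the Shannon entropy of the within-cluster cell-count
distribution. Weighted k-means is implemented in the package because
`stats::kmeans` has no observation weights; tests cross-check it against
`stats::kmeans` on count-expanded points.

## The pipeline

`run_pipeline()` ties the stages together per condition (grouping traces
by their `(que_um, ca_um)` labels, control first), computes the
cross-condition quantities (relative PSD, control-rescaled dwell entropy,
globally pooled peak entropy), and optionally writes every table as CSV
plus a JSON run manifest. Given a fixed configuration and seed, outputs
are byte-reproducible. Stage failures are trapped per condition and
recorded without aborting the remaining stages.

## What the synthetic validation does and does not show

The simulator reproduces the *statistical structure* the analyses assume —
two-level switching, alternating semi-Markov dwells, multi-exponential
versus power-law dwell distributions, Gaussian noise, 1 kHz filtering. It
does not emulate baseline drift, seal instability, capacitive transients,
subconductance levels, multi-channel patches, or amplifier nonlinearity.
Green tests therefore certify the estimators (correct formulas, exact
reconstruction, parameter recovery at known truth, deterministic
reproduction), not robustness to every artifact of bench data. Problem
sizes used in the automated checks are chosen for desk-scale runs:
dwell-mean recovery on 200 s simulations, open-probability recovery on six
1e6-sample traces, EMD validation on 200 windows of 2 000–10 000 samples,
and the end-to-end regime comparison on 3 traces of 20 s per condition;
`scripts/acceptance.R` reruns the full pipeline at that demo scale.

## Known limitations

* No missed-event correction; dwell statistics are those of the filtered,
  thresholded signal.
* Single-channel traces only; no subconductance or multi-channel
  idealization.
* EMD is the classical single-realization algorithm; ensemble variants
  (EEMD/CEEMDAN), which reduce mode mixing at a large compute cost, are
  out of scope.
* `k` is fixed by the caller (default six); the package does not select
  the number of IMF clusters automatically.
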