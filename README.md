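# scgating

Entropic, spectral, and mode-decomposition analysis of single-channel
patch-clamp recordings.

## What problem this solves

Single-channel patch-clamp recordings capture the conformational dynamics of
one ion-channel protein — for example a large-conductance Ca²⁺- and
voltage-activated potassium (BK) channel — as a noisy two-level current time
series. The standard summaries (open-state probability *p*<sub>op</sub>,
dwell-time distributions) are cumulative: very different gating mechanisms
can produce the same *p*<sub>op</sub>. This package provides the
complementary descriptors that distinguish them, for electrophysiologists
and biophysicists comparing channel behaviour across stimulation conditions
(e.g. activator concentrations):

- **Idealization** — half-amplitude thresholding of the current into
  open/closed states, *p*<sub>op</sub>, and dwell-time series.
- **Shannon entropy** of the pooled dwell-time histogram,
  *H* = −Σ*p*<sub>k</sub> log₂ *p*<sub>k</sub> (bits): how many distinct
  timescales participate in gating.
- **Sample entropy** of the dwell-time series,
  SampEn = −ln(*C*<sup>m+1</sup>/*C*<sup>m</sup>) with Chebyshev distance,
  *m* = 2, *r* = 0.2 σ: how predictable the sequence of dwell durations is.
- **Power spectra** — segment-averaged periodograms, per-condition medians,
  control-relative ratios *P̂*(f) = *P*(f)/*P*<sub>control</sub>(f), and the
  per-frequency entropy of short Hamming-window (12.8 ms, a₀ = 25/46)
  spectral peaks across time.
- **Empirical mode decomposition** of min–max-normalized 100 000-sample
  windows into intrinsic mode functions, summarized as a (frequency, energy)
  feature population, 2-D log–log histograms, and weighted k-means cluster
  summaries (centroids, occupancy, Shannon entropy; six clusters).
- **A semi-Markov gating simulator** (alternating open/closed states with
  exponential or truncated power-law dwell distributions, Gaussian noise,
  4-pole Bessel-type 1 kHz filter, 10 kHz sampling) supplying analytic
  ground truth — stationary *p*<sub>op</sub>, configured dwell laws — for
  every estimator.

## Worked example

```r
library(scgating)

model <- gating_regime("ca_high")      # strongly activated channel
model
#> <gating_model> 5 states (2 open, 3 closed)
#>   O1   open   exp(tau = 0.003 s)
#>   O2   open   exp(tau = 0.012 s)
#>   C1   closed pareto(alpha = 1.5, t_min = 0.0001 s, t_max = 0.001 s)
#>   C2   closed pareto(alpha = 1.5, t_min = 0.0001 s, t_max = 0.002 s)
#>   C3   closed pareto(alpha = 1.5, t_min = 0.0001 s, t_max = 0.005 s)
#>   levels 0/10 pA, noise 1 pA, fs 10000 Hz, cutoff 1000 Hz

stationary_open_probability(model)     # exact long-run open fraction
#> [1] 0.9554435

rec   <- simulate_recording(model, duration = 20, seed = 42)
ideal <- half_amplitude_idealize(rec$trace)
ideal
#> <idealized_trace> 'sim': 200000 samples, threshold 5.03 pA, p_op = 0.961

dwells <- extract_dwell_times(ideal)
h <- dwell_histogram(dwells)
shannon_entropy(h$probabilities)
#> [1] 4.354517
```

The measured `p_op = 0.961` recovers the analytic 0.955 through noise,
filtering, and thresholding (brief sub-resolution closings merge into
openings, nudging the estimate up). The dwell entropy, 4.35 bits over 2 762
dwells, sits below the unstimulated `control` regime (about 4.5 bits at this
scale): stabilized long openings and short power-law closings narrow the
dwell histogram. `run_pipeline()` performs these steps — plus spectra, peak
entropies, EMD features and cluster summaries — for a list of traces grouped
by condition and writes all result tables as CSV.

## Package layout

- `R/gating-model.R`, `R/simulate.R` — gating models, regimes, simulator
- `R/idealize.R` — level estimation, half-amplitude idealization, dwells
- `R/entropy.R`, `src/sampen.cpp` — Shannon entropy, SampEn (compiled core)
- `R/spectral.R` — PSDs, relative spectra, windowed spectra, peak entropy
- `R/emd.R` — sifting, IMF features
- `R/clustering.R` — 2-D histograms, weighted k-means, cluster summaries
- `R/pipeline.R`, `R/io.R` — orchestration, trace/dwell I/O
- `vignettes/single-channel-analysis.Rmd` — models, parameter choices,
  numerical conventions, limitations
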