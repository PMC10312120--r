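---
title: "Methods: single-trial beta-band dynamics and behavior"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: single-trial beta-band dynamics and behavior}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(betadyn)
```

## What this package computes

`betadyn` analyzes trial-epoched two-channel electrophysiological time
series — conventionally a "motor" and an "auditory" virtual channel — in
the beta band (13–30 Hz), and relates single-trial beta measures to
reaction times. The chain is:

1. **1/f flattening** by temporal differentiation (`differentiate()`).
2. **Single-trial spectra** (`fourier_spectra()`): Hanning taper over a
   700 ms window, zero-padded to 2 s for a 0.5 Hz grid; natural-log power.
3. **Time-frequency representation** (`tfr()`): 250 ms sliding Hanning
   windows in 20 ms steps, 13–30 Hz in 0.5 Hz steps, normalized per
   channel by the grand-mean power (`normalize_tfr()`), and collapsed to
   band-limited power time courses (`band_power_timecourse()`).
4. **Burst detection** (`burst_mask()`, `cluster_events()`,
   `burst_parameters()`): per frequency row of a single trial, points
   exceeding the within-trial mean + 2 SD that last at least one cycle
   (1/f) are clustered by time/frequency adjacency; six parameters are
   extracted per trial (event count and, for the maximal event, peak
   power, peak time, peak frequency, frequency range, time range).
5. **Instantaneous frequency** (`bandpass()`,
   `instantaneous_frequency()`): zero-phase windowed-sinc bandpass, the
   analytic signal's phase derivative, then a bank of ten median filters
   whose pointwise median is the estimate.
6. **Statistics** (`regress_timecourse()`, `shuffled_null()`,
   `cluster_permutation_test()`, `median_split()`, `paired_contrast()`):
   per-trial regression of reaction times on beta measures after
   z-scoring and |z| > 3 outlier removal; shuffled-correspondence nulls;
   group-level cluster-based permutation tests with sign-flip nulls and
   the max-|cluster-sum-t| correction; Cohen's d from cluster-averaged
   per-subject differences.
7. **Connectivity** (`ppc()`, `spectral_factorization()`,
   `granger_spectrum()`, `split_connectivity()`): pairwise phase
   consistency from trial-wise Fourier coefficients, and nonparametric
   spectral Granger causality via Wilson's factorization of the
   trial-averaged cross-spectral density, estimated separately on fast
   and slow median-split halves.

`run_pipeline()` composes all of this over simulated or stored
multi-subject datasets and emits tables where every row carries the
contrast name, cluster extent, statistic, Monte-Carlo p, and Cohen's d.

## The synthetic generator and what it emulates

Because connectivity, bursts, and regression slopes cannot be validated
on real recordings without ground truth, `make_dataset()` generates
two-channel epochs with exactly the statistical structure the analysis
assumes:

* **Background**: 1/f^α Gaussian noise (default α = 1), synthesized by
  frequency-domain amplitude shaping with uniform random phases (DC bin
  zeroed), rescaled to unit SD per trace so burst amplitudes are in
  noise-SD units. Differentiation multiplies the spectrum by roughly
  (2πf)², so α = 2 backgrounds flatten exactly and α = 1 backgrounds
  become gently rising — in both cases removing the steep low-frequency
  masking of beta-band structure.
* **Bursts**: Hanning-windowed sinusoids with Poisson counts per trial
  and channel (default rate 2 for the full pipeline; the recovery
  benchmark uses rate 1), frequencies uniform in 13–30 Hz, durations
  uniform in 2–6 cycles, uniform random phase (no phase-locking
  assumption), peak amplitude in noise-SD units (default 5). Centers
  default to −0.7..+0.1 s: the analysis grids cover −750..+250 ms, so
  bursts live where the analysis looks.
* **Directed coupling**: the auditory trace receives the bandpassed
  motor trace delayed by 20 ms, scaled by a gain that is constant when
  the coupling–RT coefficient is zero and otherwise drawn per trial from
  Uniform(0, 2·gain), giving the trial-level variance a coupling–RT
  regression needs.
* **Reaction times**: RT_i = β0 + βP·z(P_i) + βF·z(F_i) + βC·z(C_i) +
  ε_i, with P the measured trial-mean motor beta power, F the measured
  trial-mean auditory beta instantaneous frequency, C the per-trial
  coupling gain, and ε Gaussian (default SD 50 ms); RTs are clipped at a
  100 ms physiological floor. The defaults (β0 = 500 ms, βP = βF = βC =
  30 ms per z-unit) encode the three effects the pipeline must recover:
  higher motor beta power, higher auditory beta frequency, and stronger
  motor→auditory coupling all slow responses. P and F are *measured*
  from the generated traces (with deliberately simpler estimators than
  the pipeline's), not taken from the injection bookkeeping, so recovery
  is a genuine end-to-end test.

What the generator does **not** emulate: evoked responses, spatial
leakage between virtual channels, non-Poisson burst clustering,
heavy-tailed RT distributions, artifacts, or between-subject variance in
effect size (simulated subjects are exchangeable draws). Passing
parameter-recovery tests therefore demonstrates correctness of the
estimators under the assumed model, not robustness to every property of
real recordings.

## Epoch span and grids

The time-frequency grid is −750..+250 ms in 20 ms steps with a 250 ms
window, so epochs must cover −875..+375 ms. Synthetic epochs span
−1.0..+0.4 s: the left margin also absorbs the one-sample shortening and
half-sample time shift of differentiation, and the right margin covers
the final window. Note the 20 ms grid anchored at −750 ms contains
−410 ms but not −400 ms; localization tests use the nearest grid point.

## Numerical choices

* **Log power** uses the natural log; zero-power bins (possible in
  synthetic silence) are floored at the smallest positive double with a
  warning.
* **Burst thresholding** operates on normalized (not log) power, per
  frequency row, with the sample (n−1) SD, over the full TFR time axis
  of the trial; events are then assigned to the precue/pretarget window
  by the location of their peak point. Run duration for the one-cycle
  criterion counts k bins as k·20 ms. Ties at the maximal power break to
  the earliest time, then the lowest frequency. Note that the event
  *count* is not monotone in burst amplitude: a strong burst inflates
  its rows' SD and suppresses noise-floor events, which is also why a
  2 SD threshold on exponentially distributed single-taper power always
  carries a noise-event floor (about e⁻³ ≈ 5% of bins per row). The
  detector's precision against injected ground truth is bounded near
  0.35 at one injected burst per trial for this reason; recovery of
  injected bursts (recall), not raw event counts, is the quantity that
  improves with amplitude.
* **Bandpass filter**: windowed-sinc FIR, Hamming design, order = three
  cycles of the low cutoff (70 at 300 Hz for 13 Hz), applied as a single
  centered convolution on mirror-padded traces. A symmetric FIR applied
  centered is exactly zero-phase, and a single pass preserves the
  designed passband gain (|H(20 Hz)| ≈ 0.995); a forward–backward pass
  would square the response and double the edge cost for no benefit with
  a linear-phase kernel.
* **Instantaneous frequency**: analytic signal built in the frequency
  domain on mirror-padded traces (avoiding epoch-edge phase distortion),
  phase unwrapped with tolerance π, first difference scaled to Hz, ten
  median filters with kernel durations linearly spaced 10–400 ms (odd
  sample counts), pointwise median across filters. Samples within the
  largest kernel half-width of either edge, or with vanishing analytic
  amplitude, are invalidated. Group-level analyses read the series on a
  6-fold decimated time grid (one estimate per 20 ms, matching the TFR
  step) to keep subject matrices small; the estimator itself is
  sample-resolved.
* **Cluster permutation**: cluster-forming threshold is the two-tailed t
  critical value at α = 0.05 (n−1 df), clusters are contiguous
  same-sign supra-threshold runs, the cluster statistic is the summed t,
  the null is the maximum |cluster statistic| over 1000 per-subject
  sign flips, and Monte-Carlo p-values use the +1 correction. When no
  cluster forms the result reports p = 1. Multiple testing across the
  several beta measures and regions is deliberately not corrected; each
  contrast is reported with its own cluster p.
* **Wilson factorization**: performed on the full 0..Nyquist grid of the
  padded FFT (the beta band is a read-out, not the factorization
  domain), after trial averaging and ±1-bin frequency smoothing of the
  cross-spectral density (raw 0.5 Hz trial-averaged spectra can be
  ill-conditioned; the radius is exposed). Iteration stops at a relative
  update below 1e-9 or 100 iterations; non-convergence is flagged, not
  fatal, and the relative reconstruction residual ‖S − HΣH*‖/‖S‖ is
  always reported. The zero-lag splitting uses the lower-triangular
  H(0) convention. On analytic spectra the residual reaches 1e-14; on
  tapered empirical spectra it plateaus near 1e-6 because the estimate
  itself is noisy.
* **Granger accuracy**: the Hanning taper convolves the true spectrum
  with a kernel whose width scales as 1/T, biasing sharp spectral peaks;
  at 700 ms windows this bias is of order 10% at a sharp AR(2) peak and
  does not shrink with trial count. The oracle comparison in the tests
  therefore uses 2 s windows and averages the estimate over the peak
  ±2 bins; directional ordering, the quantity the analysis consumes, is
  robust at 700 ms.
* **Median split**: trials strictly below the median RT are fast, ties
  and above go slow — a fixed, deterministic rule.
* **Degenerate inputs**: zero-variance features are errors in
  `zscore_clean()` (flagged per time point in the regression), identical
  conditions give t = 0, p = 1, d = 0, while zero-variance *nonzero*
  differences are flagged undefined.

## Design choices that were genuinely open

* The TFR normalization factor is computed across trials (one scalar per
  channel); a within-trial factor would leak trial-level power into the
  normalization and distort the burst threshold.
* Diagonal time-frequency adjacency is *not* clustering adjacency
  (4-connectivity), and the one-cycle duration criterion is applied per
  frequency row before clustering, since it is defined through 1/f — a
  row-wise quantity.
* The per-participant regression null is the mean slope time course over
  100 RT reassignments; the real-vs-null test is a paired cluster test
  across subjects over time.
* The burst-recovery rule scores an injected burst as found when any
  detected event's peak lies within ±2 Hz and ±100 ms of its center, and
  an event as genuine when it matches any injection in its trial.
* The epoch container is a schema-validated serialized R object with a
  format tag; reads validate field presence, types, time-axis spacing,
  and RT length, and name the missing field on failure. Configurations
  are YAML; ground truth is JSON; tables are CSV.

## Problem sizes used in validation

The test and acceptance harnesses run, per estimator: 200 trials for
noise-slope and burst-recovery checks; 1000 simulations for the PPC
null; 100 random stable spectra for factorization residuals; 600 trials
of 2 s for the Granger oracle; 500 null simulations of 20 subjects for
cluster-test calibration; 100 seeded single-subject runs (120 trials)
for headline-effect sign recovery; and 120 seeded 8-subject null
runs (40 trials each) for false-positive calibration of the three
headline contrasts. Eight subjects give the sign-flip null 256 distinct
patterns, enough granularity for stable Monte-Carlo p-values at the
group level. These sizes give Monte-Carlo standard errors comfortably
inside the asserted bounds while keeping the default suite quick on one
core.

## Known limitations

* Exactly two channels for connectivity (bivariate factorization); no
  conditional or time-resolved Granger variants.
* No multitaper or wavelet spectral variants; nothing above 30 Hz.
* Subject-level summaries plus permutation only — no hierarchical
  models.
* The burst detector inherits the noise-event floor of its 2 SD
  threshold (see above); interpret absolute event counts accordingly.
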