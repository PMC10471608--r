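---
title: "Methods: burst detection, sigh classification, and calcium analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: burst detection, sigh classification, and calcium analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sighsort)
```

This vignette documents the models and procedures the package
implements, the conventions and numerical choices behind them, what the
synthetic-data generator does and does not emulate, and the known
limitations. Time is always seconds from the trace origin, sample
windows are half-open `[start, end)`, and all randomness flows through
explicit integer seeds, so every analysis is bit-reproducible.

## 1. Burst detection on integrated traces

The input is an already rectified-and-integrated signal (population
activity of the preBötzinger complex, or diaphragm EMG), uniformly
sampled. Detection has three rules:

* **Prominence threshold.** A peak is a burst when its topographic
  prominence exceeds `prominence_factor` (default 2.5) times the
  standard deviation of the *whole* trace. We read "SD of the
  integrated activity" literally as the full-trace SD rather than a
  baseline-segment SD: it is the simplest reproducible rule and makes
  detection invariant to adding a constant and equivariant to positive
  scaling. The consequence — worth knowing — is that the threshold
  rises with burst density and with very large events; for evoked
  sweeps the package therefore pools the SD across all sweeps of a
  recording (`classify_evoked_sweeps`), since a single 20-s sweep
  containing a sigh would otherwise blind detection within that sweep.
* **Onset at 20% of peak.** Walking backward from the peak, the onset
  is the latest upward crossing of
  `baseline + 0.2 × (peak − baseline)`. The baseline is the median of
  the trace over the inter-burst interval preceding the burst
  (`baseline = "local"`, the default) or zero (`"absolute"`); the
  median of a mostly-quiescent segment is a robust zero-level estimate
  and the choice is config-exposed because the original rule does not
  specify one.
* **Artifact rejection.** Bursts that rise from onset to peak in under
  `min_rise` (default 0.150 s) or whose peak amplitude exceeds
  `amp_factor` (default 75) times the mean peak amplitude of all
  detected bursts are flagged as noise and retained with an `artifact`
  flag for audit. Note an algebraic property of the 75× rule: with
  fewer than ~75 bursts the flagged burst's own contribution to the
  mean makes the rule impossible to trigger, so on short recordings the
  rise-time rule does the work.

### Numerical robustness devices

Two devices deal with measurement noise; both are config-exposed and
disabled by setting them to zero, and both act only on *where* the peak
and onset are placed, not on which peaks qualify.

* **Peak refinement** (`peak_refine`, default 0.25 s). Bursts of this
  preparation have flat tops, and the argmax of a noisy flat top
  jitters by tens of milliseconds. The detected peak is re-located by a
  quadratic-vertex fit to a moving-average-smoothed copy of the trace
  near the raw peak, searching no further than 40% of the gap to the
  neighbouring peaks, and falling back to the raw peak whenever the
  refined location's raw amplitude is less than half the raw peak
  (which protects narrow artifact spikes from being "refined" onto
  their smoothed plateau). Scale `peak_refine` down for rhythms much
  faster than the slice default — the in vivo EMG pipeline uses 0.03 s.
* **Onset persistence and hysteresis.** The backward walk from the peak
  stops only when the trace has stayed below the level (minus a small
  hysteresis of half the local noise scale, estimated from first
  differences) for 80 ms, then takes the first upward level crossing
  from the stop point, linearly interpolated. Without this, single
  noise dips on the rising phase — or in the inter-peak trough of a
  biphasic sigh — truncate the search and produce spuriously late
  onsets and short rises.

## 2. Burst characterization and sigh shapes

`compute_features` reports, per burst: amplitude above the local
baseline; duration from the onset-level crossing to the symmetric
return crossing (the original reports do not define burst duration
operationally; reusing the already-defined 20% level is the most
parsimonious choice, and the fraction is config-exposed); FWHM at half
the amplitude; trapezoidal area above baseline over the burst; the
post-burst interval from burst *end* to the next onset (measuring from
the end rather than the peak is the default; this too is exposed via
the computed `end_s` column); and the inter-event interval between
onsets. The last burst's interval features are missing, never zero.

`classify_shape` calls a sigh biphasic when its shape vector contains
two local maxima, each at least 20% of the global peak measured above
the burst's **local baseline**, separated by a trough at least 20%
below the smaller maximum. Measuring heights above the shape-window
minimum would be wrong in a subtle way: the window starts at the onset
(by construction a point where the trace equals 20% of peak), so the
window minimum sits near the onset level and crushes the relative
height of the biphasic small component. A 5-sample moving average
(config-exposed) precedes peak finding for noise robustness. The
classifier is only meaningful for bursts already labeled sighs;
doublets of eupneic activity are never auto-labeled sighs.

## 3. The evoked "sigh attempt" classifier

Fitted per recording, never across recordings:

1. Spontaneous burst shapes (never putative sighs, and excluding all
   optogenetically evoked bursts) are mean-centered and decomposed by
   PCA; the smallest number of leading components whose cumulative
   explained variance reaches 95% is kept. Scores are **not** whitened
   before the robust fit — the scatter estimate absorbs scale.
2. A minimum-covariance-determinant (MCD) robust location and scatter
   are fitted to the scores: seeded random (d+1)-point starts, refined
   by concentration steps to a local minimum of the subset covariance
   determinant, best of `n_restarts` (default 500) kept, support
   fraction h/n = 0.75 by default, with the usual chi-squared
   consistency correction. `support_fraction = 1` returns the classical
   estimate exactly, and the estimator matches exhaustive
   minimal-determinant search on problems small enough to enumerate
   (this is tested).
3. Each burst's Mahalanobis distance to the robust center gives
   `d_spontaneous`, and the outlier threshold is
   `median + 4 × IQR` with quartiles by linear interpolation of order
   statistics (R's quantile type 7). The threshold formula is
   convention-sensitive, so the convention is fixed and documented.
4. An identical classifier (no PCA) runs on the three intuitive
   features: amplitude, FWHM, post-burst interval. A burst whose
   post-burst interval is missing (nothing follows it) is disqualified
   from classification rather than imputed.
5. A burst is a **sigh attempt** iff it is an outlier in both
   classifiers and larger in amplitude than 90% of the spontaneous
   bursts (quantile type 7).

The whole path is invariant to uniform amplitude rescaling of the
recording — PCA scores, robust distances, and the percentile threshold
co-scale — and reproducible under a fixed seed; both properties are
tested.

## 4. The in vivo MAD rule

For each burst in the integrated diaphragm EMG, the median and MAD of
amplitude and of AUC are computed over the up-to-20 bursts before and
after (excluding the burst itself); the burst is a sigh iff both its
amplitude and AUC exceed the neighborhood median by more than 6× the
corresponding MAD (strict inequalities, so ties at zero MAD stay
eupnea). Three readings of the printed rule exist, and all are
implemented: the default compares the *signed* deviation
`value − median` (sighs are by definition unusually large; an absolute
deviation would also flag runt bursts such as a separately detected
biphasic small component, which measurably degrades precision);
`abs_deviation` and the literal `raw` value-vs-MAD comparison are
config modes. The MAD is unscaled by default (`mad_constant = 1`); no
consistency factor is stated in the original rule. Edge bursts with
fewer than 5 available neighbors are labeled eupnea. The rule is
deterministic, invariant to uniform rescaling, and a burst's label
depends only on its 40-burst neighborhood (all tested).

## 5. Calcium ROI analysis

* **z-scoring** uses the population SD (σ with denominator n), matching
  the formula's σ_F and making `[0, 2, 0, 2] → [−1, 1, −1, 1]` exact.
  Everything downstream is therefore invariant to affine rescaling of
  raw fluorescence.
* **Smoothing**: a 10-sample centered moving average, applied only when
  the sampling rate exceeds 20 Hz (the resonance-galvanometer
  convention); edges use truncated windows so constants are preserved.
* **Drug-epoch activity change**: percent difference of the signal SD
  between a 5-min baseline window and a 5-min post-drug window,
  `100 · (σ_drug − σ_base)/σ_base`.
* **Rhythmicity**: sample autocorrelation to `max_lag` (default ⅓ of
  the trace) with Bartlett large-lag standard errors. The 95%
  confidence band is **simultaneous** over the scanned lags (Bonferroni
  critical value) by default. This is a deliberate interpretation: with
  pointwise per-lag intervals the zero-crossing rule's false-positive
  rate on white noise is not controlled and *grows with trace length*
  (we measured ~14% at 300 samples and ~80% at 960 samples), because
  scanning hundreds of lags for a ±2σ excursion pair almost surely
  succeeds; with the simultaneous band the same rule is conservative at
  α = 0.05 at every length we tested while keeping full power on
  planted 10-s rhythms at SNR 2. Pointwise bands remain available
  (`simultaneous = FALSE`). An ROI is rhythmic when the band's upper
  bound first drops below zero and the lower bound later crosses above
  zero; the reported lag maximizes the autocorrelation within that
  positive excursion and the strength is the autocorrelation there.
* **Sigh-triggered tests**: per window size w ∈ {1, 2, 5, 10} s, paired
  two-sided t-tests across sighs of the mean z-scored signal in
  `[t − w, t)` versus `[t, t + w)` — the sigh onset belongs to the post
  window. Sighs whose windows spill past the trace edges are dropped
  with a warning; fewer than 3 usable sighs yields a missing result;
  zero-variance differences are flagged degenerate rather than given a
  p-value. Bonferroni multiplies by the family size m; the batch
  runner's default family is all ROIs × all windows (`"roi_x_window"`),
  matching correction across an imaging field, with a per-ROI family as
  the alternative.

## 6. The synthetic-data generator

The generator exists so that every stage can be scored against exact
ground truth. It emulates:

* eupneic bursts as difference-of-exponentials kernels
  (`tau_rise = eupnea_duration/5`, `tau_decay = 3·eupnea_duration/5`)
  recurring with a Gaussian period distribution (mean 4 s, CV 0.15 by
  default) and amplitude CV 0.08;
* sighs replacing a eupneic cycle at exponential intervals (mean 120 s),
  2.5× the eupneic amplitude, 1.5× the kernel time constants, followed
  by a doubled cycle (the post-sigh apnea), biphasic with probability
  0.785 — the control-condition biphasic fraction, a default rather
  than a constant;
* artifact spikes (< 20 ms rise), evoked sweeps with
  eupnea/sigh/failure outcomes at stated probabilities, and calcium
  ROIs (GCaMP-like transient kernels, Poisson or jittered-periodic
  event times, slow drift, a drug-epoch rate gain).

Labels carry each event's exact onset — defined, like the analysis
rule, as the 20%-of-peak crossing — computed on the *noiseless* kernel
sum, so oracle tests can re-derive them independently.

Three constructional choices deserve explanation:

* **Kernel time constants.** The default eupneic burst (0.7 s scale)
  rises from its 20% onset to peak in ~0.21 s. A much faster kernel
  (e.g. 50 ms rise constant) would rise in under 150 ms and the
  artifact rule would discard *every* burst: the 20%-onset rule and the
  150 ms artifact floor jointly constrain how fast a real burst can
  rise, and the generator respects that constraint.
* **Artifact amplitude** defaults to 20× the eupneic amplitude, not
  75×+. A 75× spike contributes so much variance that the 2.5×SD
  prominence threshold climbs past the eupneic amplitude and detection
  goes blind — whole-trace-SD thresholding only coexists with extreme
  artifacts when they are far rarer than one per few hundred seconds.
  The 20× spikes are still removed with 100% success by the rise-time
  rule, and the 75× amplitude rule is exercised on constructed burst
  tables in the unit tests. Artifacts are also placed clear of planted
  bursts (1 s behind, one full event extent ahead) so the ground truth
  stays unambiguous.
* **Biphasic geometry.** The small component is a eupnea-amplitude
  kernel whose separation from the large component is chosen per event
  (deterministically in the drawn amplitudes, minimum 0.45 s) so that
  the noiseless inter-peak trough lands midway between two hard
  boundaries: the 20%-of-peak onset level (a deeper trough would make
  the onset walk-back start *inside* the sigh and the extracted shape
  would miss the small component) and 80% of the small peak (a
  shallower trough and the two-peak rule cannot fire). The feasible
  band is narrow — roughly 0.62–0.75 of the large peak height — which
  is why a fixed separation cannot serve all amplitude draws.

What the generator does **not** emulate: burstlet activity and
desynchronized slices, amplitude drift and electrode instability,
correlated noise beyond a single integrator bandwidth (noise is
moving-average-filtered white Gaussian, 50 ms window, marginal SD
`noise_sd` = 0.1 by default, i.e. SNR 10 against the unit eupneic
amplitude), respiratory-rate modulation in vivo, and any biophysics of
the underlying neurons or astrocytes. Passing tests therefore show that
the *rules are implemented correctly and behave as designed under the
assumed statistics* — they do not certify performance on real
recordings, where the SD-based threshold in particular degrades
gracefully as noise approaches ~20% of the burst amplitude (noise
prominences then reach the detection threshold and precision falls
before sensitivity does).

## 7. Problem sizes used by the checks

The test suite and `scripts/acceptance.R` size their simulations to
give stable statistics at interactive runtimes: detection is scored on
two 20-min traces (~580 planted bursts), artifact rejection on five
5-min traces with ~4 artifacts each, the evoked classifier on 10
recordings of 25 sweeps (~75 evoked sighs, ~125 evoked eupnea), the in
vivo rule on ten 5-min EMG traces, the rhythmicity null on 1000
white-noise traces of 300 samples with 100 lags scanned, its power on
100 planted 10-s rhythms at SNR 2, and the sigh-triggered null on 500
AR(1) ROIs with 27 sighs each. MCD uses its 500-restart default in the
acceptance script and 100–200 restarts in unit tests, where the
exhaustive oracle bounds the problem size instead.

## 8. Known limitations

* The whole-trace-SD prominence threshold couples detection to burst
  density and event magnitude; recordings with frequent very large
  events need the pooled-SD route (or an explicit `sd_value`).
* The 95%-variance PCA truncation keeps several dozen components on
  noisy shapes (noise variance is spread isotropically), which makes
  the MCD fit higher-dimensional than strictly necessary; it still
  separates sighs by orders of magnitude in D, but a variance floor per
  component would be a reasonable extension.
* The rhythmicity rule reports a single dominant lag; nested or
  multiple rhythms per ROI are out of scope.
* `classify_sighs_invivo` assumes bursts are supplied in temporal
  order and that the rolling neighborhood is stationary at the 40-burst
  scale; abrupt gain changes mid-recording should be split into epochs
  first.
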