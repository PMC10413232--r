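---
title: "Cardiac force index processing and G-tolerance prediction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Cardiac force index processing and G-tolerance prediction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gtol)
```

## The measurement problem

Sustained head-to-foot acceleration (+Gz) drains blood from the head;
when cerebral perfusion fails, a pilot suffers G-induced loss of
consciousness. Centrifuge training measures two thresholds per person: the
**relaxed G tolerance** (RGT), the G level at slow onset (0.1 G/s)
producing defined visual loss with no countermeasure, and the **straining G
tolerance** (SGT), the same endpoint while performing the anti-G straining
maneuver, administratively capped at the 9 G training ceiling.

The **cardiac force index** (CFI) is a wearable-derived proxy for how much
mechanical load the cardiovascular system moves per beat. From a 1 Hz
chest-strap record of heart rate (HR, bpm) and activity (the
vector-magnitude acceleration of a triaxial accelerometer, in g),

\[
\mathrm{CFI}_t \;=\; \frac{\text{weight} \times \text{activity}_t}{\mathrm{HR}_t}
\qquad [\text{kg} \times \text{G} / \text{bpm}],
\]

averaged over a 2-minute window at seated rest (**RCFI**) and during
relaxed walking (**WCFI**); their ratio **CFR = WCFI / RCFI** is a
dimensionless walking-to-rest contrast. This package implements the whole
chain — stream reading, confidence-based quality control, protocol
segmentation, window averaging — together with the published linear
equations predicting RGT and SGT from WCFI and demographics, a stepwise
OLS fitter, and a calibrated synthetic-data generator that stands in for
the (unavailable) raw study data.

## Signal quality and windows

The device flags each second with an HR-confidence and a system-confidence
percentage. Seconds where **either is strictly below 20%** are dropped
(`quality_filter()`); 20% is the vendor's reliability floor and equality
keeps the sample. Dropped seconds are removed, not interpolated: window
means divide by the number of valid seconds actually present, which is
unbiased under missingness that is unrelated to the signal. A participant
whose rest or walk window retains less than 80% of its 120 seconds is
excluded (`run_process()`). The 80% floor is this package's choice — the
study reports excluding 6 of 219 participants for poor quality without
stating its criterion.

The ground protocol is 5 minutes of seated rest, a squat bout, 3 minutes
of relaxed walking, and a second squat bout. The squats exist precisely to
mark the walk in the activity trace, so `detect_squat_markers()` finds
maximal runs (≥ 3 s) of activity above 3× a 61-second rolling median —
robust to the rest-to-walk baseline shift and to between-person activity
scale — merges runs closer than 60 s (a bout split by signal dropout is
one bout), and returns run midpoints. Segmentation (`segment_phases()`)
then places:

* **rest window**: the final 120 s before the first squat bout (HR is most
  settled just before it), ending 3 s before the detected spike onset —
  a single leaked squat second carries ~75× the resting CFI and would
  dominate the mean, and thresholded onset detection can run a second or
  two late;
* **walk window**: the central 120 s of the inter-bout span, excluding
  gait transients at either end, with the start floored to whole seconds
  so a full-coverage window holds exactly 120 samples.

With fewer than two markers the nominal protocol clock is used
(rest `[180, 300)`, walk `[340, 460)`). The source protocol states only
that 2-minute averages were taken; which two minutes, and how the squats
were used computationally, are this package's documented choices.

## The prediction models

The published equations (G; WCFI enters on the ×100 scale exactly as
estimated):

\[
\widehat{\mathrm{RGT}} = 0.066\,\text{age} + 0.043\,(\mathrm{WCFI}\times100)
 - 0.037\,\text{height} + 0.015\,\mathrm{SBP} - 0.010\,\mathrm{HR} + 7.724
\]
\[
\widehat{\mathrm{SGT}} = 0.103\,(\mathrm{WCFI}\times100)
 - 0.069\,\text{height} + 0.018\,\mathrm{SBP} + 15.899
\]

`predict_rgt()` / `predict_sgt()` take natural-scale WCFI and rescale
internally to prevent unit mistakes; inputs beyond the development-cohort
ranges warn rather than fail, because the linear model extrapolates
smoothly even where it is unvalidated.

The fitting machinery is self-contained: `fit_ols()` solves least squares
by QR and derives SEs, two-sided t p-values and 95% CIs from the residual
variance and \((X'X)^{-1}\); its agreement with `stats::lm` and with a
closed-form simple-regression oracle is enforced in the test suite.
`fit_stepwise()` is the classical p-value-driven procedure (entry .05 /
removal .10, the convention of the statistics package the study used —
the thresholds themselves are not reported). Ties break by candidate
order, then name; requiring `p_remove >= p_enter` excludes add/remove
cycling. With ~9 null candidates at `p_enter = .05`, forward selection
admits a noise covariate with probability ≈ 1 − 0.95^9 ≈ 0.37 even at
n = 100,000 — entry p-values are uniform under the null — so "selects
exactly the true set" holds only seed-by-seed; this is a property of
stepwise selection, not of the implementation.

`compare_observed_estimated()` is a paired t-test with both vectors'
means and SDs. For in-sample OLS predictions the mean difference is
identically zero (residuals sum to zero), so the reported p-values of the
source's observed-vs-estimated table cannot arise from that test; the
package implements the standard test and documents the discrepancy rather
than guessing the source's procedure.

## The synthetic cohort generator

`simulate_cohort()` emulates the study conditions so every stage is
testable without raw data. Design choices, in decreasing order of how
strongly the source pins them down:

* **Covariates** (age, height, weight, SBP, DBP, resting HR) are jointly
  Gaussian at the reported means/SDs, truncated to the reported ranges by
  joint rejection sampling. The reported age range (22–27) is narrower
  than one SD (3.66) around its mean and cannot be the sampling support;
  age truncates to a wide plausible range (16–45) instead. The
  vitals-by-CFI correlation block uses the reported Pearson matrix;
  anthropometry cross-correlations are unreported and take plausible
  defaults (height–weight .5, small age effects), all configurable. The
  assembled matrix is repaired to the nearest positive-definite
  correlation matrix (`nearest_pd_repair()`, Higham) when needed; the
  default assembly is already PD and needs no repair.
* **(RCFI, WCFI)** are jointly log-normal. Five reported moments — mean
  RCFI 0.016, mean WCFI 0.141, SD WCFI 0.037, mean CFR 10.76, SD CFR
  4.38 — pin down the five log-scale parameters in closed form
  (`calibrate_cfi_lognormal()`). Log-normality is forced by the data: the
  mean per-person ratio (10.76) exceeds the ratio of means (8.81), which
  no jointly Gaussian model with the reported moments reproduces. Two
  consequences are accepted and documented: the implied log-scale
  RCFI–WCFI correlation (.78) overrides the reported natural-scale .329
  for that single pair, and the implied RCFI SD (~0.0097) replaces the
  reported 0.001, which is internally inconsistent with the reported
  RCFI range 0.006–0.088.
* **Outcomes** follow the published equations plus Gaussian residuals.
  Residual SDs come from the observed/estimated SD split,
  \(\sqrt{0.9^2-0.4^2}=0.806\) (RGT) and \(\sqrt{1.06^2-0.5^2}=0.935\)
  (SGT) — an assumption, since the split is all the source reports. SGT
  is censored at the 9 G ceiling with capped rows flagged. Intercepts are
  recalibrated so the *population* outcome means equal the observed 4.9
  and 7.9 G: the printed 3-decimal slopes evaluated at the printed
  covariate means give 4.83/7.93 (the source's own estimated-vs-observed
  table shows the same rounding gap), and for SGT the calibration solves
  the censored-mean equation. Because covariate truncation slightly
  shifts the correlated latent components, all location calibrations are
  taken against the truncated latent distribution, whose moments are
  estimated once per configuration by a fixed-seed internal Monte Carlo
  (300,000 draws; deterministic, and the caller's RNG state is
  preserved).
* **Streams** (`synthesize_stream()`): rest 300 s, squat 10 s, walk
  180 s, squat 10 s, tail 30 s at 1 Hz. Walking HR defaults to resting
  + 20 bpm (consistent with walking HR below ~120 bpm); HR carries AR(1)
  jitter (ϕ = .9, stationary SD 2 bpm). Per-second activity is inverted
  from the participant's target CFI and the realized HR
  (activity = CFI × HR / weight) with 5% multiplicative noise, so the
  pipeline mean is unbiased for the target and per-window recovery error
  has SD ≈ 0.05/√120 ≈ 0.46%. Squat bouts emit 1.5 g spikes — well above
  any walking vector magnitude (≤ ~0.35 g in this cohort), keeping the
  3×-median detector's margin physical. Each second drops below the 20%
  confidence floor with probability 0.02, the same order as the study's
  6/219 exclusions would suggest for sporadic signal loss.

What the generator does **not** emulate: real accelerometer spectra and
gait dynamics, HR drift and arrhythmia, device-specific confidence
behaviour, or any biophysics of G tolerance. Passing recovery tests
therefore demonstrates that the *pipeline arithmetic* is correct under
the stated noise model, not that the device or the physiology behaves
this way.

## Numerical and degenerate-input conventions

All windows are half-open, 0-based, integer-second aligned. Duplicate or
non-monotone timestamps are ordering errors (a broken session clock), not
row-level rejections; malformed rows are rejected with row-indexed
diagnostics and the reader never silently drops data. The vendor's
"HR 0 at confidence 0" no-reading convention is normalized to an invalid
sample on read. Zero-variance columns yield undefined correlations
(reported as such, never fabricated); zero-variance paired differences
report p = 1 and are flagged degenerate. Rank-deficient designs are
refused naming the collinear columns. G-tolerance histograms use
half-open 0.5 G bins from 3.0 G with the 9.0 G ceiling as its own
terminal bin.

## Problem sizes used in the checks

The shipped checks run 200 cohorts of n = 213 for generator calibration
(grand means of WCFI, RCFI, CFR, RGT, SGT within 1% of target), one full
213-participant stream cohort for end-to-end recovery (every participant
within 2%, exact at zero noise), and one n = 100,000 cohort for stepwise
parameter recovery — sizes at which the calibration tolerances are
several standard errors wide while the whole suite stays fast.

## Worked example

```{r example}
cfg <- sim_config(n = 25)
sim <- simulate_cohort(cfg, seed = 7)
streams <- simulate_streams(sim)
proc <- run_process(streams, sim$cohort)
head(proc$summaries[c("id", "rcfi", "wcfi", "cfr")], 3)

# published-equation predictions for the processed participants
merged <- merge(proc$summaries, sim$cohort[c("id", "height", "sbp")])
head(predict_sgt(merged$wcfi, merged$height, merged$sbp), 3)
```

## Known limitations

* The reported correlation matrix is a *target*, not a guarantee: the
  lognormal CFI pair and the truncation of the vitals bend realized
  correlations away from the printed values (most visibly RCFI–WCFI).
* The stepwise exact-recovery property is probabilistic across seeds, as
  discussed above.
* The observed-vs-estimated p-values of the source cannot be reproduced
  by any in-sample paired t-test; the package makes the standard test
  available and leaves the discrepancy documented.
* CFI is measured on the ground only; nothing here models under-G
  physiology, and no claim about preventing G-induced loss of
  consciousness in flight follows from these tools.
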