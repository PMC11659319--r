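---
title: "Methods: ABR wave features as biomarkers for cognitive performance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: ABR wave features as biomarkers for cognitive performance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(abrcog)
```

## The problem

Age-related cognitive decline lacks biomarkers that are cheap, objective and
repeatable. The auditory brainstem response (ABR) — the scalp potential
evoked in the first ~10 ms after a click — is a candidate: its wave V
(lateral lemniscus / inferior colliculus) latency reflects synaptic delay
and conduction speed, and its amplitude the number and synchrony of
responding neurons. `abrcog` implements the full analysis chain for asking
whether wave V features predict cognitive performance in an adult cohort
over and above age: feature extraction from raw sweeps, composite cognitive
scoring, covariate-adjusted association models, a percentile-criterion
ROC/AUC sweep with Youden-optimal cutoffs and a chance band, and k-fold
cross-validated discriminant classification. A synthetic-cohort generator
with known ground truth makes every stage testable without any participant
data.

## The synthetic cohort generator

`cohort_params()` encodes a cross-sectional design with three age groups
(young 18–30, middle-aged 31–59, elderly 60–92 years; n = 26/26/66). Within
each group age is uniform on the group's range — the simplest distribution
respecting the design's bounds when only means, SDs and ranges are known.
The generating models are linear with Gaussian residuals:

* **PTA** (pure-tone average, dB HL): intercept −8.7, slope 0.44 dB/year,
  residual SD 9 dB, floored at −10 dB HL. Group means land near
  3 / 13 / 23 dB HL.
* **Wave V latency** (ms): 5.873 + 0.00334·age, residual SD 0.28 —
  group means near 5.95 / 6.01 / 6.11 ms.
* **Wave V amplitude** (µV): 0.353 − 0.0023·age, residual SD 0.10, floored
  at 0.005 µV — group means near 0.30 / 0.25 / 0.19 µV.
* **Wave I** is age-independent (latency 1.80 ± 0.26 ms, amplitude
  0.10 ± 0.09 µV), reflecting the absence of a wave I association in this
  design.
* **Cognition**: a latent composite (z units) that is linear in age and in
  the population-standardized wave V features, with slopes −0.101 z per z of
  latency and +0.110 z per z of amplitude and residual SD 0.45 z.

One modelling subtlety deserves emphasis. The parameter the user sets as the
cognition *age slope* (−0.021 z/year) is the **marginal** composite-on-age
slope — what an unadjusted regression recovers. Because the wave V features
themselves depend on age, the generator derives the *direct* age coefficient
internally by subtracting the ABR-mediated pathway. With this
parameterization all three headline slopes are simultaneously recoverable:
the univariate age slope (−0.021), and the age-adjusted latency (−0.101) and
amplitude (+0.110) slopes.

The ten cognitive measures are generated as a single shared factor (the
latent composite) plus independent noise (SD 0.76 z per measure), mapped
onto each measure's native scale and direction: trail-making A/B and the
spatial-test reaction time are time-based, so lower raw values are better.
No further inter-measure correlation structure is imposed — with ten
measures and one factor, the scored composite then tracks the latent one
with a small attenuation-free measurement error (noise enters the outcome,
not the predictors, so association slopes stay unbiased).

**What passing tests do and do not show.** The generator emulates the
*statistical* structure the analysis assumes: linear age trends, a shared
cognitive factor, Gaussian residuals, complete data by default (an optional
missingness rate exists). It does not emulate floor/ceiling effects in the
raw tests, heteroscedastic hearing loss in the elderly, inter-measure
correlations beyond the shared factor, or selection effects in recruitment.
Recovery of the generating parameters therefore validates the estimation
machinery, not the biological claims.

## Raw epochs and feature extraction

`generate_epoch_set()` builds sweeps-by-samples matrices at 24 kHz (chosen
to leave comfortable margin above twice the 3000 Hz analysis corner) over a
10.66 ms epoch. Each wave is a zero-integral biphasic complex: a positive
Gaussian at the configured latency minus an equal-width Gaussian 3.5 widths
later, normalized so its peak-to-trough equals the configured amplitude.
Two properties motivated this shape over a plain positive bump: real ABR
waves are a peak followed by a trough, and a zero-DC complex passes the
100 Hz high-pass corner essentially undistorted (a plain Gaussian loses
~20% of its peak there). The trough offset of 3.5 widths keeps the trough
lobe's slope at the peak below ~0.01 width, so the realized maximum sits at
the configured latency to well within one sample. Artifact sweeps carry an
added 2 ms square excursion (default 50 µV); only its exceedance of the
23.8 µV rejection threshold matters.

The default single-sweep noise is 2 µV white Gaussian: after rejecting
artifacts, averaging ~1900 sweeps and bandpassing, the residual noise of the
averaged waveform is ~0.02 µV, the level typical of clinical ABR averages.

Processing mirrors standard practice:

1. `reject_artifacts()` drops sweeps whose absolute maximum exceeds
   23.8 µV. It only changes the accepted mask, so it is idempotent.
2. `average_and_filter()` averages accepted sweeps and applies a zero-phase
   4th-order Butterworth bandpass (100–3000 Hz), implemented as cascaded
   high-pass and low-pass sections run forward–backward. Zero-phase
   filtering leaves peak latencies untouched (verified to within one
   sample). The short epoch is zero-padded by its own length on each side
   before filtering to suppress edge transients; this is principled because
   the evoked response is ~0 at the epoch edges. Fewer accepted sweeps than
   the advisory minimum (2000) warn rather than fail so that small test
   fixtures run.
3. `pick_wave()` takes the latency as the time of the window maximum
   (wave I: 1.3–2.3 ms; wave V: 5.1–6.4 ms) and the amplitude as peak minus
   the following trough. The trough is the first local minimum within 2 ms
   after the peak **that holds over a ±0.5 ms neighbourhood** — the
   neighbourhood requirement exists because a sample-level local minimum is
   noise-fragile: at realistic residual noise, shallow dips on the falling
   flank otherwise masquerade as the trough and halve the measured
   amplitude. When no such minimum exists the minimum over the 2 ms span is
   used. QC flags (`no-peak`, `boundary-peak`) replace the manual peak
   confirmation a human scorer would perform; flagged records should be
   reviewed or excluded by the caller.
4. `extract_features()` adds the I–V inter-peak latency difference and the
   natural-log V/I amplitude ratio (missing when either amplitude is zero).

At the default noise the *latency* of a single recording still wanders by
~0.2 ms SD, because the argmax of a broad peak is noise-sensitive — this is
precisely why clinical practice confirms peaks manually, and why the
planted-peak recovery contract (one sample, 10% amplitude) is stated at low
residual noise (≤ 0.05 µV per sweep at 2000 sweeps).

## Scoring

The PTA is the mean audiometric threshold over 0.5/1/2/4 kHz per ear; the
better (lower-PTA) ear is used, ties going to the right ear with a logged
note. Age groups break at 18–30/31–59/≥60 years and hearing loss is
PTA ≥ 20 dB HL (strictly below 20 is normal).

Each cognitive measure is z-scored against the analyzed sample (n − 1
denominator) and sign-flipped where lower raw scores are better, so higher z
always means better performance. The composite is the mean over a
participant's available z-scores when at least 8 of 10 are present;
otherwise the participant is flagged excluded. Two deliberate choices: the
z-scoring population is the full analyzed sample (group analyses reuse
full-sample z-scores), and the lower-is-better set is exactly
{trail-making A, trail-making B, spatial-test reaction time}, inferred from
measure semantics.

A consequence of within-sample standardization worth knowing: because the
composite's scale is renormalized against each realized sample, the
sampling variance of, e.g., the composite-on-age slope is slightly smaller
than its OLS standard error suggests, so confidence intervals on the scored
composite are mildly conservative (~98% realized coverage at n = 118 in
simulation, vs the nominal 95% which holds for the latent composite). The
calibration tests therefore target the generator's latent cognition
variable; the conservativeness of the scored composite is asserted
separately.

## Association models

`fit_linear_model()` is ordinary least squares with t-based 95% CIs and
two-sided p-values for the named predictor, enforcing at least 10
observations per independent variable. Age enters in raw years when the
outcome is in z units (so the age slope reads "z per year"); ABR and hearing
predictors are standardized to sample z units; a binary hearing category
stays 0/1. `model_diagnostics()` reports residual normality (Shapiro–Wilk),
heteroscedasticity (Breusch–Pagan), linearity (RESET) and variance inflation
factors with pass/warn status (warn at p < 0.05, VIF > 5); diagnostics never
auto-reject a model — they are surfaced for the analyst.
`run_association_suite()` crosses the composite and all ten domain z-scores
with the auditory predictors, univariate and age-adjusted, in the full
sample and per age group, continuing past per-model failures (failed rows
keep the error message). No multiplicity correction is applied across the
suite; the only Bonferroni correction is the one tied to the age-group
post-hoc comparisons in `compare_age_groups()`.

## The percentile ROC sweep

For each percentile criterion p = 1..99 on the composite (linear
interpolation quantile, R type 7; participants at or above the cutoff are
"good performers"), the oriented predictor's empirical AUC is the
Mann–Whitney probability that a random good performer out-scores a random
poor one (ties count ½), computed from midranks. The Youden-optimal cutoff
maximizes sensitivity + specificity − 1 over all midpoints between adjacent
unique scores (±∞ included), breaking ties toward higher specificity and
then the lower cutoff; cutoffs are reported in the predictor's original
units with their decision direction (latency above the cutoff predicts
poor; amplitude above it predicts good).

Predictor orientation is fixed a priori per feature — amplitude up = good,
latency up = poor — never chosen as max(AUC, 1 − AUC), which would bias the
curve upward. Age adjustment residualizes only the labeling variable (the
composite) on age; the predictor is left raw.

The chance band replaces the predictor with independent standard-normal
draws per replicate (default 1000, seeded). Because the AUC is invariant
under monotone transforms, any continuous null distribution yields the same
band, making this null distribution-free. Two dispersions can be quoted and
they differ by an order of magnitude: the SD of the grid-mean AUC *across
replicates* (~0.05 at n = 118 — a single random predictor's whole-curve mean
varies this much) and the SD *across percentiles* of the replicate-averaged
curve (~0.002). Both are reported.

Comparisons between two sweep curves (e.g. raw vs age-adjusted) use a paired
two-sided t-test across the common grid points, with the explicit caveat
that the 99 grid points are strongly dependent, so the p-value is
descriptive.

## Cross-validation

`cv_sweep()` repeats the sweep with k-fold cross-validation (k ∈ {2, 5, 10}
by convention, enforced unless overridden): one random, non-stratified,
seeded fold assignment shared across percentiles; per fold, a one-feature
linear discriminant with pooled within-class variance is fit on the training
folds and its discriminant score computes the validation AUC. A fold whose
training *or* validation labels are single-class is excluded (the
discriminant, or sensitivity/specificity, is undefined there) and counted;
percentiles with zero retained folds are reported missing. Non-stratified
folds are deliberate: at extreme percentiles (1–2 minority labels among
118), fold degeneracy is expected and the exclusion bookkeeping is part of
the method.

Because a one-feature linear discriminant's score is monotone in the
feature (direction given by the sign of the training-class mean difference),
each fold's AUC equals the raw-feature AUC on the validation fold under that
orientation — an exact oracle used by the tests at 1e−10. The discriminant
is computed in closed form rather than through a general LDA routine for
two reasons: a posterior-probability score saturates to ties at extreme
separations (breaking the oracle identity in floating point), and
single-member classes in tiny folds are legitimate inputs here. An
established LDA implementation is used as an independent cross-check in the
test suite.

## Numerical and policy choices, collected

* Quantile type 7 (linear interpolation) for percentile cutoffs.
* Sample SD uses n − 1 throughout.
* Missing-composite rule: ≥ 8 of 10 measures, else excluded.
* Filter: cascaded 4th-order Butterworth, forward–backward, zero-padded.
* Trough: first ±0.5 ms-neighbourhood local minimum within 2 ms; fallback
  span minimum; amplitudes reported as non-negative magnitudes.
* Youden ties: higher specificity, then lower cutoff.
* Degenerate percentile labelings are missing points, not failures.
* All generators take explicit seeds and restore the caller's RNG state;
  identical (parameters, seed) give byte-identical outputs.

## Problem sizes used in the test suite

The suite exercises the study design at its natural size (n = 118
cohorts; 99-point percentile grids; 1000-replicate chance band; 1000
random AUC oracle instances; 200 replicate cohorts for CI calibration;
100 epoch sets of 2000 sweeps for planted-peak recovery). Larger
simulations (e.g. n = 2000 slope recovery) use single cohorts. These sizes
were chosen so the whole suite completes in a couple of minutes while
keeping Monte-Carlo error far below the tested tolerances.

## Known limitations

* Automated peak picking plus QC flags replaces human confirmation; on
  noisy averages the argmax latency wanders where a human would interpolate.
* The deposited per-participant data of the motivating study are consumed
  through an explicit column map (`load_source_data()`); the workbook's
  internal layout is unknown until opened, so the map must be edited by the
  user — nothing is guessed.
* Waves II–IV, latency-intensity functions and multi-feature classifiers
  are out of scope.
* The chance band's "randomly generated predictor" is i.i.d. standard
  normal; a permutation null of the observed predictor is provided in tests
  and agrees to Monte-Carlo error.
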