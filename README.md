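# abrcog

Auditory brainstem response (ABR) wave features as biomarkers for cognitive
performance in adults.

## What this package is for

In aging cohorts, cognition declines with age and covaries with hearing
loss, and recent evidence ties it to the brainstem's evoked response: the
ABR wave V latency (ms from click onset to peak) and amplitude
(peak-to-following-trough, µV). `abrcog` implements the complete analysis
chain for a cross-sectional study of this question, for researchers in
audiology, cognitive aging and biostatistics:

* **Feature extraction** from raw epoch matrices: rejection of sweeps
  exceeding 23.8 µV, zero-phase 100–3000 Hz Butterworth bandpass,
  averaging, windowed peak picking (wave I 1.3–2.3 ms, wave V 5.1–6.4 ms)
  with QC flags, I–V latency difference and log V/I amplitude ratio.
* **Scoring**: pure-tone average (0.5/1/2/4 kHz) and better ear; ten
  cognitive measures z-scored and direction-adjusted (higher = better);
  composite z as their mean; age groups (18–30/31–59/≥60) and hearing
  categories (PTA ≥ 20 dB HL = loss).
* **Association models**: OLS with t-based 95% CIs, univariate and
  age-adjusted, e.g. composite ~ age gives B in z/year; assumption
  diagnostics; the full outcome × predictor suite; age-group GLM with
  Bonferroni post-hocs.
* **Percentile ROC sweep**: for each percentile criterion p = 1..99 on the
  composite, good/poor labeling at the empirical quantile, the oriented
  predictor's empirical AUC (Mann–Whitney probability, ties ½), and the
  Youden-optimal cutoff (max sensitivity + specificity − 1); a chance band
  from 1000 random standard-normal predictors; an age-adjusted variant that
  residualizes the composite on age.
* **Cross-validation**: per percentile, a one-feature pooled-variance
  linear discriminant over k ∈ {2, 5, 10} random folds, with single-class
  folds excluded from the average exactly as the degenerate-fold rule
  requires.
* **A synthetic cohort generator** with known ground truth (three age
  groups n = 26/26/66; marginal cognition-age slope −0.021 z/year;
  age-adjusted wave V latency/amplitude slopes −0.101/+0.110 z per z), so
  every stage is testable end to end, plus a raw-sweep generator with
  planted waves and artifacts.

The statistic at the core of the sweep is the empirical AUC: for good
performers G and poor performers P on an oriented biomarker X,

    AUC = Pr(X_G > X_P) + 1/2 · Pr(X_G = X_P),

estimated from midranks, and the optimal cutoff c* maximizes Youden's
J(c) = sensitivity(c) + specificity(c) − 1.

## Worked example

The `analysis/` scripts run the whole study on a synthetic cohort and write
tables under `results/`. Running them in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_features.R
Rscript analysis/03_associations.R
Rscript analysis/04_roc_sweep.R
Rscript analysis/05_crossval.R
```

prints, among other things (seed 20260925):

```
cohort: 118 participants (elderly n=66, middle n=26, young n=26)

wave V:  latency 5.917 ms (planted 6.05), amplitude 0.258 uV (planted 0.23), qc clean

composite associations (full sample):
  age                raw        B =  -0.020  [ -0.024,  -0.016]  p = 5.241e-17
  pta                age-adj    B =  -0.087  [ -0.242,   0.067]  p = 0.2641
  wave_v_latency     age-adj    B =  -0.168  [ -0.263,  -0.072]  p = 0.0007045
  wave_v_amplitude   age-adj    B =   0.106  [  0.002,   0.211]  p = 0.04596

wave_v_latency_raw                 mean AUC 0.70 (sd 0.05, range 0.52-0.90)
wave_v_amplitude_raw               mean AUC 0.71 (sd 0.05, range 0.53-0.81)
chance band: mean AUC 0.499 (sd across replicates 0.050, across percentiles 0.002)

wave_v_latency_raw_k2        CV 0.66 (sd 0.11) vs classical 0.70 (p = 0.0076)
```

Reading these: cognition drops ~0.02 z per year of age; after age
adjustment, hearing level carries no extra information about cognition but
both wave V features still do (longer latency ⇒ worse, larger amplitude ⇒
better). Both features separate good from poor performers well above the
chance band across the whole percentile range, and the 2-fold
cross-validated discriminant reproduces the same pattern with the expected
slight shrinkage. On a synthetic cohort these statements are recoveries of
planted effects, not findings.

In code, the same pipeline is three calls:

```r
library(abrcog)
g      <- generate_cohort(cohort_params(seed = 1))
scored <- score_cohort(g$cohort)
run_sweep(scored, "wave_v_amplitude", orientation = "higher_better")
#> <sweep_curve> wave_v_amplitude (higher_better): mean AUC 0.702 (sd 0.050,
#>   range 0.599-0.849), peak at percentile 98, n = 118
```

`run_pipeline(pipeline_config(...))` executes every stage and writes the
result CSVs, a plain-text report and a manifest with content digests.

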