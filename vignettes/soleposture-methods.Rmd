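---
title: "Methods: center-of-pressure posturography from insole pressure"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: center-of-pressure posturography from insole pressure}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The measurement model

A pressure insole reports, at each sampling instant, one force value per
anatomical zone — eight zones here, from the big toe to the lateral heel.
The center of pressure (COP) under one foot is the force-weighted centroid
of the zone coordinates:

$$
COP_{ML} = \frac{\sum_{i=1}^{8} F_i\, D_{ML,i}}{\sum_{i=1}^{8} F_i},
\qquad
COP_{AP} = \frac{\sum_{i=1}^{8} F_i\, D_{AP,i}}{\sum_{i=1}^{8} F_i},
$$

with $F_i$ the zone forces and $(D_{ML,i}, D_{AP,i})$ the mediolateral /
anteroposterior zone coordinates in mm. The COP trajectory over a balance
trial (the stabilogram) is the raw material for every downstream feature.
Insole vendors do not publish their zone coordinates, so the geometry is an
explicit, configurable parameter (`zone_geometry()`); the default is an
anatomically plausible layout on a ~100 x 250 mm footprint. Within one
consistent geometry, all dispersion and dynamics features are exact; only
the absolute position of the mean COP depends on the chosen origin.

The ML sign convention is positive = lateral for each foot, so left and
right feet are mirror-consistent and across-feet comparisons are
meaningful.

**Validity masking.** The centroid is undefined when the total force
vanishes — swing phases in gait, the lifted foot in one-foot stance. Frames
whose total force falls below a threshold (default 5% of the trial's median
total force) are marked invalid and *dropped* from every feature, never
interpolated or zero-filled: interpolation would fabricate sway where the
foot was airborne, and zero-filling would inject spurious spectral power.
Dynamic features differentiate each contiguous valid run independently;
gaps never contribute finite differences.

## Acquisition chain

The study hardware streams at 50 Hz (some units at 12 Hz). For rate
consistency, 50 Hz data are anti-alias filtered and resampled to 12 Hz:
an order-4 Butterworth low-pass at 0.4 x the target rate, applied
forward-backward (an effective order-8 zero-phase filter), then linear
interpolation onto the 12 Hz grid. Zero-phase filtering is used because
phase distortion would bias the timing-sensitive dynamic features;
odd-reflection padding suppresses start-up transients so DC (static load)
passes with unit gain. Jittered timestamps are first regularised by linear
interpolation onto a uniform grid, since the spectral estimators assume
uniform sampling.

## The 60-feature bank

Sixty features per foot and task, partitioned 19 positional / 21 dynamic /
20 spectral. The inventory follows the classical stabilometry literature
(the Prieto positional and spectral sets plus the sway-density family);
the full list with formulas is in the documentation of
`positional_features()`, `dynamic_features()` and `frequency_features()`.
Choices worth flagging:

* **95% confidence ellipse** — $\pi\,\chi^2_{0.95,2}\sqrt{\det\Sigma}$
  with $\Sigma$ the sample covariance ($\chi^2_{0.95,2} = 5.991$); axes
  and orientation from its eigendecomposition.
* **Sway density** — for each instant, the time spent by consecutive
  samples inside a 3 mm circle around the current COP. The curve is
  smoothed with a 0.5 s moving average before peak extraction (the radius
  is the literature value; the smoothing window is a package default).
  Peaks index stable postural episodes; we report their mean height and
  the mean spatial and temporal separation of successive peaks.
* **Velocities** — central finite differences at the sampling rate,
  one-sided at run boundaries.
* **Spectra** — Welch's method: Hann window of `min(128, N/2)` samples,
  50% overlap, per-segment linear detrend, one-sided scaling so the PSD
  integrates to the variance (checked against Parseval in the tests).
  Segments are taken within valid runs; when every run is shorter than
  the window (gait stance phases), the valid samples are concatenated and
  the per-segment detrend absorbs the junction offsets. Band energies
  (< 0.5 Hz, 0.5–2 Hz, > 2 Hz) are reported as fractions of total power.
* **Mean frequency (hybrid)** — mean speed / (2$\pi$ x mean distance),
  which recovers $f$ exactly for a pure sinusoid.

Features undefined on degenerate input (a constant trajectory's median
frequency, fewer than 2 valid frames) carry `NA` markers, never silent
zeros; before modeling they are imputed by column medians.

**Across feet.** Per feature, the average $(L + R)/2$ and the asymmetry
$|L - R|/(L + R)$ are formed — 120 features per task, 720 over the six
tasks. The asymmetry ratio lies in $[0, 1]$ for non-negative features; for
signed features (e.g. mean value ML) the denominator can be non-positive.
We compute the ratio exactly as defined and attach a flag naming the
affected features rather than silently redefining the formula, since any
redefinition (absolute values in the denominator, say) would change the
measurand. For the one-foot stance task only the weight-bearing foot is
informative: the left-stance and right-stance segments of the trial give
the "left" and "right" vectors, and the combination is a between-stance
average/asymmetry.

**Normalization.** Min-max scaling to $[0, 1]$ per column. The default
fits the scaler once on all subjects, replicating the single global
scaling of typical study pipelines; a leakage-safe mode re-fits inside
every cross-validation training fold. The global default is deliberately
simple: its optimism on small cohorts is real but modest (the
scaler uses only per-feature extrema), whereas the pre-filter is the
larger leakage channel — which is why the leakage-safe evaluation mode is
provided and recommended for honest error estimates.

## Selection, classification, evaluation

1. **ANOVA F pre-filter** — per feature, the one-way F statistic between
   the two classes; features with $p > 0.05$ are removed. This is a
   pruning device, not an inference procedure.
2. **Forward sequential feature selection** — greedy path over the
   survivors; at each step the feature maximising the 5-fold
   cross-validated F1 of the classifier at default hyperparameters is
   appended. The optimal subset is the path prefix with the highest CV
   F1; ties break by column order. The full path ("until all features
   have been added") is the default; a `max_features` cap bounds the
   $O(p^2)$ path cost for large feature sets, and the experiments in this
   package's validation suite use caps of 3–10 on cohorts of 12–20
   subjects, where the optimum is invariably reached within the first few
   steps.
3. **Tuning** — exhaustive grid search by the same CV F1 on the fixed
   subset, after selection (matching the stated order of the reference
   stack). Default grids are package choices: SVM cost 0.1/1/10 x
   linear/RBF; RF 100/300 trees, node size 1/5; ridge logistic
   $\lambda$ 0.01/0.1/1; KNN $k$ 3/5/7/9; GNB variance smoothing
   1e-9/1e-7.
4. **Evaluation** — stratified 5-fold CV; accuracy, precision, recall,
   F1 and Cohen's kappa per fold, averaged with standard errors; ROC
   curves vertically averaged on a common 101-point FPR grid with mean
   AUC ± SEM. One fold partition is shared by all five architectures so
   task-set comparisons are paired. Out-of-fold predictions are retained
   for misclassification analysis.
5. **Task-set comparison** — fold-level metrics modeled with task set and
   architecture as fixed effects (architecture as a blocking factor);
   the three pairwise comparisons use a Bonferroni-corrected threshold
   of $0.05/3 = 0.017$. A fixed-effects linear model is used rather than
   a mixed model because the random-effect structure of the reference
   description is under-specified and, with five architectures as a
   complete block, the fixed blocking factor is the identifiable
   equivalent.

The classifier families are SVM (e1071), random forest (randomForest),
ridge-penalised logistic regression (glmnet, matching the L2/C
parameterisation of the reference stack), KNN (class), and a Gaussian
naive Bayes written in-package so that the variance-smoothing
hyperparameter is tunable.

## Interpretation

* **Common features** — features appearing in at least 3 of the 5
  architectures' optimal subsets.
* **Shapley values** — exact interventional Shapley attribution of the
  positive-class score: coalitions enumerated exhaustively (feasible for
  the small optimal subsets produced by SFS), out-of-coalition features
  replaced by background rows (the model's training rows). Local accuracy
  holds exactly; null players get exactly zero. A seeded
  permutation-sampling estimator covers larger subsets. Each model's "top
  Shapley feature" is the feature with the highest mean $|\phi|$ over the
  evaluation subjects — the mean-absolute aggregation is our choice among
  the defensible readings of "single highest Shapley value".
* **Key features** — the unique names at the intersection of the common
  sets and the top-Shapley sets across the static, active and
  static+active analyses.
* **Misclassification** — subjects wrong (out-of-fold) under at least 3
  of 5 architectures.
* **z-scores** — features standardised by pooled mean/SD, then averaged
  within group, so group values are directly comparable (the polar-plot
  construction).

## The synthetic cohort generator

Real insole recordings from a clinical cohort cannot ship with a package;
the generator exists so that every stage is testable against known ground
truth. Effects are injected in *latent COP space*, not feature space, so
all 60 features respond coherently the way physiology would:

* Static sway is a stationary 2-D process: white noise band-limited below
  3 Hz per axis, plus a < 0.5 Hz component whose weight a `low_band_gain`
  scales and a 3–5.5 Hz component scaled with `zero_crossing_gain`; the
  mixture is rescaled to the configured sway SD, so spectral-shape gains
  change band fractions without changing total power. Means are the
  configured ML/AP offsets.
* Active tasks add deterministic templates: a smooth AP excursion for
  functional reach; an AP excursion with a 30% force dip for bending
  over; alternating 0.7 s stance / 0.5 s swing windows with a heel-to-toe
  AP sweep and a double-bump force profile for gait (the two feet half a
  cycle apart).
* Right-foot parameters are the left's scaled by `asymmetry_gain`,
  plus small per-subject jitter (lognormal ~10% SD on sway SDs, 1 mm
  between-subject SD on offsets, ~3% jitter on the gain itself).
* Trials follow the study protocol durations: 30 s quiet-stance trials
  (one-foot stance 30 s per foot), with 10 s gait and 6 s reach/bend
  trials as realistic active-task lengths.
* Zone forces are rendered from the latent COP by minimum-norm
  non-negative least squares under three equality constraints (total
  force, ML and AP centroid), solved for all frames at once through a
  precomputed pseudo-inverse with an active-set fix-up for frames near
  the hull; the round trip back through `compute_cop()` reproduces the
  latent COP to better than $10^{-6}$ mm, so rendering adds no bias.
* Simulation runs at the native 50 Hz and recordings pass through the
  same anti-alias/down-sample chain as real data.

The presets encode direction patterns reported for parkinsonian posture
(lateral ML shift, larger sway, EO/BO asymmetry for PD vs control;
raised EC zero-crossing rate, gait ML low-band power and EC asymmetry for
fallers vs non-fallers); the magnitudes are simulation choices, not
clinical claims.

**What the generator does not emulate** — and hence what passing tests do
not show about real data: tremor peaks and medication cycles, foot-shape
and fit variability, turning segments in gait, non-stationary fatigue
drifts, sensor noise and drop-outs, and realistic between-subject effect
overlap. Passing recovery tests demonstrate that the *pipeline* is
correct and sensitive, not that real cohorts separate this cleanly.

## Numerical choices and degenerate inputs

* COP frames need total force above threshold; an all-invalid recording
  is an error naming the recording.
* The asymmetry ratio at $0/0$ is 0 (no asymmetry in an absent
  quantity); any other zero denominator is `NA`.
* Constant columns min-max normalize to 0; constant trajectories have
  zero total power and `NA` median/mode frequencies; detrend residue
  below $10^{-14}$ mm$^2$ counts as zero power.
* SFS and grid ties break to the first candidate in column/grid order,
  making every run reproducible; all stochastic stages (folds, forests,
  sampling estimators) are seeded.
* Segments shorter than 5 frames are discarded in one-foot stance
  segmentation (a brief touch-down is not a stance).

## Validation problem sizes

The package's own validation (tests and the acceptance script) uses
cohorts of 2–10 subjects per group, single-task or reduced task sets for
the selection-stack experiments, SFS caps of 3–10 features, 20-seed
recovery replications, and 50-seed null calibrations — sizes at which
every documented tolerance is met and the full suite runs in minutes on
one CPU. The pipeline itself has no such limits; `run_all()` on a
40-subject six-task cohort is the intended scale of use.

## Known limitations

* The 60-feature inventory reproduces the published feature *names* and
  the 19/21/20 partition, but the source's exact formulas live in its
  supplementary code; where a formula is not pinned down by the name we
  follow the standard literature definition and document it. Replacing
  the inventory is supported.
* Clinical headline numbers (AUC ≈ 0.99 on real PD cohorts) are not
  reproducible from synthetic data and are out of scope here; an adapter
  for the published cohort data is possible but not bundled.
* The fixed-effects stand-in for the task-set comparison model treats
  folds as independent; with five architectures sharing one fold
  partition the residual correlation makes its p-values mildly liberal.
* KNN uses uniform vote weights (the `class` implementation); a
  distance-weighted variant is not provided.
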