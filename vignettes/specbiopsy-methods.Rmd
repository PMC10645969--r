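---
title: "Methods: simulation and nested cross-validation for spectroscopic liquid biopsies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: simulation and nested cross-validation for spectroscopic liquid biopsies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(specbiopsy)
```

## The problem this package models

A serum ATR-FTIR diagnostic measures one absorbance spectrum per aliquot
over the mid-infrared range; each patient sample is measured several times
(nine replicates here), and a supervised model converts replicate spectra
into a patient-level cancer call. Because patient data of this kind are
generally not publishable, the package pairs the evaluation machinery with
a synthetic cohort generator so that every statistical property of the
pipeline — calibration under the null, recovery of injected signal,
leakage-freedom, threshold-tuning behaviour — can be demonstrated and
tested end to end on data whose ground truth is known exactly.

## The synthetic cohort generator

A spectrum is built as

```
scatter * (base(λ) + effects(λ, group, stage)) + drift(λ) + ε(λ)
```

- `base(λ)`: a sum of Gaussian (optionally Lorentzian) bands,
  parameterized by center (cm⁻¹), FWHM (cm⁻¹) and peak absorbance. The
  default library places the dominant serum features — Amide A ~3290,
  CH stretches ~2960/2872, Amide I ~1655, Amide II ~1530, Amide III ~1260,
  PO₂⁻ ~1240/1080, carbohydrate ~1025 cm⁻¹ — with amplitudes chosen to
  resemble a vector-normalized serum spectrum qualitatively. They are not
  quantitative; no attempt is made to reproduce real absorbance values.
- `effects`: each cancer group adds signed Gaussian perturbations at the
  wavenumber regions reported as discriminatory for that organ
  (`default_class_effects()`), scaled per stage by (0.5, 0.75, 1.0, 1.25)
  for Stages I–IV. The stage scaling encodes the standard narrative that
  early-stage disease carries weaker circulating signal; no quantitative
  model for it exists, so the multipliers are a design choice, fixed once.
  The default effect amplitude is 5× the replicate noise sd — a regime in
  which signal is recoverable but not trivial. Between-class effect sizes
  in real cohorts are unknown; simulated AUCs are therefore properties of
  these settings, never predictions of real-data performance.
- Noise model: i.i.d. Gaussian noise per point (`noise_sd`, absorbance
  units, default 0.01), one second-order polynomial baseline per spectrum
  (`drift_amplitude`, default 0.005) and one multiplicative scatter factor
  per spectrum (`scatter_sd`, default 0.01) — the standard benchtop FTIR
  artefact set. Deliberately absent: Mie/EMSC scattering physics, water
  vapour lines, detector nonlinearity, instrument drift between batches.
  Passing tests therefore demonstrate correctness of the *statistics*, not
  robustness to every real-world spectral artefact.
- Grid: 4000→452 cm⁻¹ at 4 cm⁻¹ (888 points), a typical benchtop
  resolution. 450 cm⁻¹ is not commensurate with the 4 cm⁻¹ step, so the
  grid ends at the last on-grid point, 452.

The metadata layout is fully deterministic given the group sizes: stages
are allocated by largest remainder (so 1534 cancer patients under the
default 231:516:410:377 proportions give exactly those counts), sex
alternates within mixed-sex groups (ovarian is all-female, prostate
all-male), and ages are evenly spaced quantiles of a Normal(60, 12) years
distribution clamped to [18, 95]. Only the spectra consume the master
seed, via per-patient child seeds hashed from (seed, patient index); this
makes cohorts extensible without reshuffling and lets two seeds share an
identical metadata layout while differing in every spectrum.

## Preprocessing

The recipe is fixed-order — truncate → baseline → derivative → normalize —
and entirely per-spectrum, which rules out train/test leakage by
construction (nothing is fit across spectra). Defaults: windows 3700–2700
∪ 1800–1000 cm⁻¹ (skipping the CO₂/quiet region), rubberband baseline,
vector normalization, no derivative — a conventional serum-FTIR recipe;
all choices are swappable through `preprocess_params()`. The rubberband
baseline is the lower convex hull through the spectrum endpoints (Andrew's
monotone chain, linearly interpolated), guaranteeing corrected values
≥ −10⁻⁹; baseline and Savitzky–Golay steps are applied per contiguous
window segment so disjoint windows are never bridged. Savitzky–Golay
derivatives require a uniform grid and a window longer than the polynomial
order; violations are errors, not warnings.

## Classifier

The default estimator is a random forest of probability trees (ranger):
robust to the strong collinearity of spectral features, natively
probabilistic, and equipped with impurity importances. A regularized
logistic family (glmnet) sits behind the same interface. Scores are always
the probability of the case class; importances are clipped at zero and
normalized to sum to one. The default tuning grid is deliberately small —
200 trees, depth {4, 8, unlimited}, minimum node size {1, 5} — sized for
desk-scale experiments; the grid is part of the experiment config, and a
single-row grid skips hyperparameter search entirely (threshold-only
tuning).

## Nested cross-validation

Outer loop: `n_resamples` (default 51) random 70:30 patient-level splits.
Splits are stratified by class — a design choice, since unstratified 30%
test draws can lose a class entirely and make per-resample ROC undefined.
The train count per class is `round(0.7 · n)`, clamped to keep at least
one patient per class on each side. All nine replicate spectra of a
patient stay on one side of every split.

Inner loop: five patient-level folds on the training set (stratified,
dealt within class). Each hyperparameter setting is scored by the mean
out-of-fold patient AUC, where a patient's score is the median of its
replicate scores. The winner's pooled out-of-fold patient scores feed the
threshold search.

Threshold selection: candidates are midpoints between adjacent distinct
scores plus ∓∞ sentinels; a patient is called a case when its score
strictly exceeds the threshold. Among candidates whose target metric
(cross-validated sensitivity or specificity) is at least the configured
minimum (0.90 / 0.45 presets for organ-specific tasks, 0.98 for pooled
tasks), the threshold maximizing the complementary metric wins; exact ties
go to the higher threshold. Because the sentinels give sensitivity 1 at
−∞ and specificity 1 at +∞, a minimum below 1 is always attainable; the
documented fallback (maximize the target metric) can only trigger for a
minimum of exactly 1 under pathological score sets. A consequence of the
tie rule worth knowing: with fully separable, distinct scores the selected
threshold leaves the *target* metric exactly at its minimum (e.g. CV
sensitivity 0.90) with the complementary metric at 1 — both thresholds are
optimal, and the rule prefers the stricter one.

Consensus: each replicate votes at the threshold; majority wins, and the
(even-count-only) vote tie goes to *case*, consistent with a rule-out
triage test that prioritizes sensitivity. For odd counts the consensus
call equals thresholding the median replicate score — verified
exhaustively over all 2⁹ vote patterns in the test suite — so the median
is used as the patient score, making voting and patient-level ROC mutually
consistent.

Aggregation: per-resample test sensitivity/specificity/AUC are summarized
by mean ± sd; 95% CIs are percentile intervals (2.5th–97.5th) across
resamples, a distribution-free choice suited to 51 replicates. The mean
ROC is computed by vertical averaging: each resample's patient ROC is
linearly interpolated onto a fixed 101-point FPR grid (upper envelope at
tied FPRs), TPRs are averaged pointwise, and a final running maximum
guards monotonicity against interpolation jitter; the mean AUC of the
averaged curve is its trapezoid area. Every per-patient test prediction is
retained for downstream metadata analysis.

## Evaluation layer

ROC curves enumerate all distinct thresholds with tied scores grouped;
trapezoid AUC then equals the tie-corrected Mann–Whitney statistic
U/(n₁n₂) — asserted against an O(n²) pairwise oracle at 10⁻¹² in the test
suite. Detection rates follow the post-hoc design: a patient's rate is
correct calls / test-set appearances (expected appearances under 51
resamples at 30% test fraction: 15.3); category rates are unweighted means
over patients, pooled rates are size-weighted means of category
percentages, and percentages are rounded half-up (floor(x + 0.5)), the
conventional presentation rule rather than R's banker's rounding.
`ppv_at_prevalence()` applies Bayes' rule; it is reported alongside, and
distinguished from, the empirical test-set PPV, since the latter reflects
the artificial case:control mix of the evaluation cohort. Printed
PPV figures in this literature are generally *not* recoverable from
rounded sensitivity/specificity pairs (the inputs lose precision before
Bayes' rule is applied), so the package treats analytic PPVs as
illustrative, not as reproduction targets.

## Feature importance

Per-resample importance vectors (on the post-preprocessing grid) are
averaged pointwise, the mean renormalized to sum to 1, with sd tracked per
wavenumber. Top regions are found by greedy peak-picking with a ±30 cm⁻¹
suppression half-width (a typical band width); exact ties break toward the
higher wavenumber. Peaks are labelled from a non-overlapping lookup of
tentative biomolecular assignments shipped as an editable YAML
(`extdata/band_assignments.yaml`). For derivative features the importance
is attributed to the feature's wavenumber; no spectral deconvolution is
attempted. The importance metric is model-native (impurity or |coef|);
permutation importance was considered and left out to keep the per-resample
cost linear in the grid size.

## Numerical and I/O choices

- Absorbances are serialized with 12 significant digits, so a CSV
  round-trip reproduces a cohort to well below 10⁻⁹ absorbance even for
  order-1 values.
- Degenerate inputs fail loudly: all-zero spectra cannot be
  vector-normalized, constant spectra cannot be min-max scaled, one-class
  inputs are rejected by ROC/threshold/confusion functions, ascending
  wavenumber grids and duplicate (patient, replicate) rows are format
  errors, and a failed resample aborts the experiment naming its index —
  partial results are never emitted silently.
- All randomness flows from one master seed through deterministic child
  seeds (multiplicative-congruential mix, kept within 32-bit range) for
  patients, splits, folds and model fits; ranger runs single-threaded with
  a fixed seed so whole experiments are bit-reproducible.

## Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at
deliberately desk-scale sizes, chosen once as representative: null
calibration uses a zero-effect cohort of 60 vs 60 patients (9 replicates,
11 outer resamples, single-row grid), and signal recovery uses 40 vs 40
patients with effects at 1530 and 1080 cm⁻¹ at 5× the noise sd — injected
with flat stage scaling so the stated amplitude is exact. The worked
detection-rate checks use the printed per-stage counts (231/516/410/377
patients; 213/438/375/359 correct) as inputs to the detection-rate
machinery. Full-scale settings (51 resamples, the 3×2 hyperparameter grid)
remain the defaults of `run_task()` and are exercised structurally.

## Known limitations

- The simulator's band-level effect model cannot calibrate real-world
  effect sizes; simulated performance bounds nothing about real cohorts.
- The preprocessing of the originating platform is unpublished; the
  defaults here are conventional, explicit and swappable, but not a
  reconstruction.
- Only binary contrasts are supported; multi-class tumour-of-origin
  prediction is out of scope.
- The consensus tie rule and the strict-inequality threshold convention
  are choices isolated behind `consensus_predict()` and
  `select_threshold()`; alternative conventions would change metrics only
  at exact-tie boundaries.
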