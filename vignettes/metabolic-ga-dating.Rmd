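---
title: "Metabolic gestational age dating: models, simulation design and validation methodology"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic gestational age dating: models, simulation design and validation methodology}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metabGA)
```

## The problem

Where first-trimester ultrasound is unavailable, the gestational age (GA) of
a newborn is usually guessed from late-pregnancy measurements or postnatal
scoring systems that err by 2–4 weeks. Newborn-screening dried blood spots
offer an alternative: many routinely measured analytes — amino acids,
acylcarnitines, TSH, 17-OHP, and especially the ratio of fetal to adult
hemoglobin — vary systematically with gestational maturity. Regression
models built on screening panels from large North American birth cohorts can
date a newborn to roughly one week RMSE, and the pressing methodological
question is how such models behave when transported to a different
population, to cord blood instead of heel-prick blood, and to data with
missing analyte values.

`metabGA` implements that entire validation exercise as reusable, tested
code: a seeded cohort simulator playing the role of the (non-public)
screening datasets, the three-model hierarchy, multiple imputation with
pooled scoring, and the validation surfaces (RMSE, within-±k-week accuracy,
SGA-stratified performance, residual diagnostics, preterm ROC/AUC,
calibration-slope adjustment).

## The model hierarchy

All three models estimate continuous GA in weeks by penalised linear
regression:

* **Model 1 (baseline)** — clinical covariates only: infant sex, multiple
  birth (yes/no), birthweight (g).
* **Model 2 (analyte)** — sex and multiple birth, plus the analyte panel and
  pairwise analyte interactions; birthweight is deliberately excluded.
* **Model 3 (full)** — the union of the two.

Fitting is elastic net (`glmnet`, mixing parameter $\alpha = 0.5$) with
10-fold cross-validation choosing $\lambda$ at minimum CV error and a seeded
fold assignment, so every fit is exactly reproducible. The intercept is
never penalised. Continuous predictors are standardized on the training set;
interaction columns are products of the standardized main effects, and the
stored centering/scaling is applied verbatim at prediction time, so a
serialised model (`write_ga_model()`) reproduces its predictions to
round-off after reload.

Two design choices deserve comment because the underlying literature leaves
them open:

* **Interaction scope.** "All pairwise interactions" over a 47-analyte panel
  is 1,081 columns; the package defaults to all pairs among the seven
  analytes that dominate the GA signal (fetal/adult hemoglobin ratio, TSH,
  17-OHP, alanine, C5, C4DC, tyrosine — `strong_analytes()`), with
  `interaction_pairs = "all"` available. This keeps the default design at
  ~70 columns while retaining the terms that could plausibly matter.
* **Sample-type handling.** Heel and cord cohorts are fit and scored
  separately rather than pooled with a sample-type covariate, because
  heel-prick and cord blood differ systematically (postnatal TSH surge,
  delivery-related 17-OHP elevation) and published validations report the
  two streams separately.
* **Analyte transformation.** Whether source models log-transformed
  analytes is not documented; `log_transform` is exposed on `model_spec()`
  and defaults to off.

## What the simulator emulates

The simulator (`simulate_cohort()`) generates record-level tables with the
statistical structure the models exploit. Its defaults are fixed study
conditions, not tuning knobs:

* **Gestational age** is a two-part mixture: with probability
  `preterm_target_fraction` (default 0.09) an infant is preterm with
  $GA = 37 - E$, $E$ a truncated exponential tail (mean 1.8 wk, support
  (0, 11]); otherwise GA is normal truncated to [37, 43] wk whose parameters
  are solved numerically so the *marginal* mean and SD hit the configured
  39.1 ± 1.6 wk. This reproduces the heavy term skew of field cohorts while
  keeping the printed moments exact.
* **Birthweight** is linear in GA with a ±40 g sex shift, anchored so the
  term and preterm conditional means match the configured 2900 g / 2330 g,
  with residual SD 395 g, truncated to [300, 6000] g. Alternatively,
  birthweight can be drawn directly from a reference chart
  (`birthweight_chart`), which is how the SGA rate-recovery property is
  exercised.
* **Sampling design**: a configurable fraction of infants (default 0.42)
  contributes both a heel and a cord sample sharing all clinical
  covariates; unpaired infants split heel/cord by `unpaired_heel_fraction`
  (default 0.054, reflecting a field setting where cord collection is far
  easier than heel prick). Heel collection age is normal 15.0 ± 6.5 h
  truncated to [0.4, 40.5] h; cord collection is 0.06 ± 0.25 h truncated at
  2.1 h.
* **Analytes** follow
  `intercept + slope_ga * (GA − 40) + slope_age * age + cord_shift * [cord] + noise`,
  truncated at zero. Noise is split between a latent factor shared within an
  infant's analyte group (weight `correlation_strength`, default 0.3) and
  independent error; the shared factor induces both cross-analyte
  correlation within biochemical groups and cord–heel correlation within an
  infant, which is what makes imputation non-trivial. The default effect
  table (`default_analyte_effects()`) gives the seven strong predictors
  slopes of the physiologically expected sign (hemoglobin ratio and the
  endocrine markers fall with GA; alanine and tyrosine rise; TSH surges
  postnatally, so it separates heel from cord means) and leaves most of the
  panel as weakly informative background. The magnitudes are **calibration
  constants of the simulator**, chosen once so that a refit full model
  attains a heel RMSE of about one week at a training size of 5,000 infants
  — they are not published assay effect sizes, and no published coefficient
  values exist to copy.
* **Missingness** is MCAR at a per-cell rate of 0.00125 (≈5.7% of samples
  with ≥1 missing analyte), capped at 5 of 47 analytes per sample; a
  MAR-by-sample-type option (cord cells at 0.35× the heel rate) supports
  sensitivity checks, and `inject_fully_missing` plants a 100%-missing
  sample to exercise the screening exclusion.

What the simulator does **not** emulate: assay chemistry, plate and
instrument drift, congenital-disorder screen positives, informative
missingness tied to clinical state, or the true (unpublished) multivariate
analyte distribution. Passing tests therefore demonstrate that the
*pipeline* is correct and that the models behave as the theory predicts on
data with this structure — not that the package reproduces any real
cohort's numbers.

## Reference charts and SGA

SGA10/SGA3 are calls of birthweight strictly below the 10th/3rd percentile
within categories of completed gestational week (floor of GA) and sex —
"below" is read as a strict inequality, and SGA3 ⊆ SGA10 by construction.
The default chart is a Gaussian location/scale family per (sex, week)
consistent with the simulator's birthweight model, covering weeks 24–43;
the delimited-text chart format lets users substitute a real population
reference. The published validations used an (uncited) North American
reference; since that chart is not printed anywhere, the module stays
chart-agnostic.

## Missing data

Screening (`screen_samples()`) excludes samples whose missing fraction
reaches the threshold (default 1.0 — only fully missing samples drop,
matching the single 100%-missing cord sample excluded in the motivating
study) and flags the rest for imputation.

Imputation (`impute_missing()`) is chained-equations stochastic regression:
each incomplete analyte is regressed on all other analytes plus sex,
birthweight, multiple birth and sample type via ridge-regularised least
squares (ridge rather than OLS so the sweep is well-posed even with more
predictors than observed rows in small cohorts), and missing cells are
replaced by prediction plus a Gaussian residual draw; three sweeps, m = 10
copies, fully seeded. Gestational age is deliberately **excluded** from the
conditioning set because it is the downstream prediction target; whether
the original analysis conditioned on it is not documented, so the package
takes the conservative choice and records the method tag in the imputation
manifest so alternatives can be swapped.

Pooling follows one rule everywhere: compute the quantity per imputation,
then average — predictions, RMSE, AUC and CI bounds as means
(`pool_scalar()`), counts as the mean rounded to the closest integer, half
away from zero (`pool_count()`). Rubin-style variance combination is out of
scope because only pooled point metrics are reported.

## Validation metrics

* **RMSE** is the standard root mean square of (predicted − observed); an
  informal gloss of RMSE as "average absolute deviation" sometimes appears
  in figure captions, but the root-mean-square definition is the one
  implemented.
* **Within-±k weeks** uses a closed interval (a residual of exactly k
  counts as within), with percentages to one decimal; under MI the counts
  are pooled by the count rule.
* **Residual diagnostics** report predicted − observed by observed GA with
  category means for <37, 37–42 and >42 wk. Because penalised regression
  shrinks toward the training mean, an external cohort with a wider GA
  range than training shows the characteristic regression-to-the-mean
  pattern — positive mean residual (overestimation) in preterm infants,
  negative (underestimation) post-term. The test suite constructs exactly
  this situation and checks the sign pattern.
* **Preterm discrimination** scores each sample with the negated pooled GA
  prediction (lower predicted GA = more preterm-like) against the observed
  <37-week label. AUC is the midrank Mann–Whitney statistic (identical to
  trapezoidal area under the empirical ROC with tie interpolation); the
  test suite verifies equality with an exhaustive pairwise-comparison
  oracle to 1e−12 on 500 random tied instances. The 95% CI uses the DeLong
  variance estimator by default (a seeded stratified bootstrap is the
  alternative); which method the motivating study used is unstated, and
  DeLong is the conventional default. Under MI, AUC and CI bounds are
  pooled by averaging.
* **Recalibration** (`recalibrate()`) regresses observed on predicted GA;
  a slope below 1 flags overdispersed predictions. Adjusted predictions are
  `intercept + slope × prediction`. This implements the
  calibration-in-the-large / calibration-slope adjustment that external
  validations recommend when models transported to new populations show
  the residual pattern above.

## Numerical choices and degenerate inputs

* Zero-variance design columns are dropped with a warning before fitting;
  a constant outcome or single-class ROC label set is an error, not a
  silent 0/NaN.
* Empty strata in reports keep `n = 0` with `NA` metrics rather than
  fabricated zeros.
* Count pooling breaks .5 ties away from zero so pooled counts are
  parity-independent.
* The GA mixture solver uses Nelder–Mead on (μ, log σ) against closed-form
  truncated-normal/exponential moments; the match is exact to optimizer
  tolerance (≈1e−6 wk).
* All randomness flows from explicit integer seeds; a single pipeline seed
  is fanned out to stage seeds by a fixed affine map mod 2³¹ − 1, so stages
  are individually rerunnable (`analysis/` scripts) while the end-to-end
  run is byte-identical across repeats.
* Prediction clipping to a GA range is available but off by default, since
  residual diagnostics are more informative unclipped.

## Problem sizes

The packaged analysis and acceptance script use a development cohort of
5,000 infants (paired heel + cord), an external cohort of 1,500 infants
(≈600 heel / 1,450 cord samples), and m = 10 imputations — large enough
that the model hierarchy ordering (full < analyte < baseline external RMSE)
and the ≈1-week full-model RMSE are stable across seeds, and small enough
that the whole pipeline completes in well under a minute. Unit tests use
cohorts of 20–6,000 as each property requires.

## Known limitations

* Synthetic analyte effects are linear and Gaussian; real screening panels
  have skewed, heteroscedastic distributions and nonlinear GA dependence,
  so absolute metric values here characterise the pipeline, not any real
  population.
* The imputation model is linear-Gaussian chained equations; it is
  well-calibrated for the simulator's own data-generating process but is
  not a general-purpose MI engine.
* The default reference chart is a stand-in consistent with the simulator,
  not a population growth standard; SGA rates on real data require a real
  chart file.
* Only pooled point metrics are produced across imputations;
  between-imputation variance is not propagated into the reported CIs.
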