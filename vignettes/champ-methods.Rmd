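---
title: "Missingness-adaptive mortality prediction for HEMS cohorts: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Missingness-adaptive mortality prediction for HEMS cohorts: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(champr)
```

## The problem

Physician-staffed helicopter emergency medical services (HEMS) attend a wide
range of critically ill and injured patients. Benchmarking such services
requires a severity-of-illness estimate comparable to the ICU scores (APACHE,
SAPS), but computed from what is actually measurable at the scene — and
pre-hospital records are notoriously incomplete: a cardiac-arrest patient has
no oxygen saturation to measure, and vital signs are missing far more often
among patients who die. `champr` implements a complete development and
internal-validation pipeline for a CHAMP-style (Critical HEMS Algorithm for
Mortality Prediction) 30-day mortality estimator that confronts this
missingness head-on, plus a synthetic cohort generator so every stage can be
exercised and tested without access to any registry.

## The model

The core model is a multivariable logistic regression for death within 30
days of the encounter. Eleven predictors survive screening: systolic blood
pressure, heart rate, oxygen saturation, GCS, sex, age, vehicle type
(helicopter vs ground unit), whether the mission was located in a medical
facility or nursing home, a binary arrest-rhythm indicator (VF, VT, asystole
or PEA vs any other observed rhythm), time from emergency call to HEMS
arrival, and the dispatch category.

Continuous predictors enter through restricted cubic splines: `k` knots give
`k - 1` regression columns, the first being the variable itself and the rest
truncated-power cubic terms constrained to be linear beyond the boundary
knots. GCS gets three knots, the other five continuous predictors four, so
the full design has 29 non-intercept columns (5×3 spline + 2 GCS + 4 binary
+ 8 category indicators against the merged reference). Before basis
evaluation, every continuous variable except GCS is winsorized at its
empirical 1st and 99th percentiles — values beyond the limits are set to the
limit itself — which also caps the cubic tails at scoring time. GCS is
exempt: it is already a bounded 3–15 integer scale.

Knot locations sit at fixed quantiles of the training data: (0.10, 0.50,
0.90) for three knots and (0.05, 0.35, 0.65, 0.95) for four. These are the
conventional defaults when only the knot count is prescribed; none of the
package's tests depend on the exact placement rule.

## Screening

Three rules run before modelling, all on marginal frequencies only:

* a variable is dropped when more than one third of it is missing
  (respiratory rate and time to first-EMS arrival fall here);
* a categorical level below 2% prevalence is dropped — for a two-level
  structure that removes the variable (the "two or more patients" level,
  prevalence ≈ 1.7%);
* a level with under 2% 30-day mortality is merged away (gynaecology/
  obstetrics, with infection also below the prevalence cut-off; the two
  merge into `infection_or_gyn_obstetrics`, which becomes the regression
  reference group).

Missingness fractions are computed over all records, including the ones
whose outcome is itself missing. Whether the original screening excluded
missing-outcome patients first is not documented anywhere we could rely on;
counting everyone is the choice that uses the same denominator as the
published missing-data counts. The raw rhythm variable is screened on its
modelled binary form, so its rare raw levels (paced, isolated extrasystoles)
are absorbed by the collapse rather than triggering drops. "Not registered"
rhythm is treated as an observed non-arrest state coding 0 on the indicator
— it is recorded separately from "missing" in registry practice — with
`not_registered_as_missing = TRUE` available for the alternative reading.

Note that the within-level mortality of the psychiatric/intoxication
category sits essentially *on* the 2% cut-off (≈ 2.1%) in the published
frequencies, so in finite synthetic cohorts that level occasionally merges
too. This is a faithful property of the emulated population, not a defect;
the retained 11-predictor set is unaffected.

## Missing data

Imputation is by chained equations: `m` completed datasets (default 30),
each produced by `maxit` sweeps (default 10) over the incomplete variables
in order of increasing missingness. Conditional models are predictive mean
matching with 5 donors for continuous variables, a Bayesian logistic draw
for binaries, and a polytomous logistic draw (fitted on a bootstrap
resample, so parameter uncertainty propagates) for unordered categories.
PMM imputes GCS from observed donors, so imputed values are automatically
integers in 3–15. The outcome participates both as predictor and as
imputation target (`include_outcome = TRUE`), mirroring a cohort whose
outcome linkage is itself incomplete; records with missing outcome are still
excluded from performance metrics. Convergence is inspected, not
auto-tested: the returned object carries per-iteration chain means and SDs,
and no automatic stopping is attempted.

Estimates across completed datasets are pooled by Rubin's rules: the pooled
estimate is the mean; the total variance is the mean within-imputation
variance plus `(1 + 1/m)` times the between-imputation variance. Pooled
covariance matrices use the full between-imputation covariance — not only
the diagonal — because the block Wald tests need the off-diagonals.
Confidence intervals for odds ratios use the normal 1.96 multiplier; at
m = 30 the Barnard–Rubin small-sample correction is negligible (the pooled
degrees of freedom are returned for anyone who wants it).

One deliberate design choice: the winsorization limits and knots are
estimated **once**, from the first completed dataset, and shared by every
per-imputation fit. Pooling coefficients that refer to different spline
bases would mix incompatible parametrisations; freezing the transform makes
the pooled coefficient vector exactly the object the exported registry
evaluates. Within a bootstrap validation loop the transform is re-estimated
inside every resample, so its optimism is still captured.

## The ensemble

The five predictors with the most missing data — systolic blood pressure,
heart rate, oxygen saturation, GCS and the arrest-rhythm indicator — are
"droppable": one submodel is fitted for every subset of them, 2⁵ = 32
models, each built in exactly the same manner as the full model and
restricted to its own variables. At scoring time the algorithm selects the
submodel whose inclusion mask equals the record's availability pattern, so
every observed droppable variable is used and no missing one is. The six
remaining predictors are required: a record missing, say, age is rejected
with an explicit reason rather than silently imputed at scoring time, since
the published model bank only covers the five named variables.

The fitted bank exports to a versioned JSON registry (droppable order,
frozen limits and knots, category levels, per-model coefficient vectors and
optionally covariances) that round-trips predictions to near machine
precision, supporting standalone scoring.

## Performance and internal validation

Discrimination is AUROC (midrank formula, ties counted half) with a DeLong
placement-variance CI. Overall accuracy is the Brier score. Calibration is
summarised by the slope of the free logistic recalibration of the outcome on
the predicted log-odds, and by calibration-in-the-large — the intercept of
the same regression with slope fixed at 1 — the standard pairing when a
single "slope and intercept" pair is reported. The Hosmer–Lemeshow test uses
ten risk deciles (`df = groups - 2`; the group count is configurable since
the canonical choice is convention, not doctrine), and the calibration curve
is a penalized-spline logistic smoother (a GAM) of the outcome on the
predicted log-odds, evaluated on a 100-point grid with pointwise bands.
Algorithm-level performance is computed on the original, non-imputed cohort
using availability-based selection — the authentic user experience — with
missing-outcome records excluded.

Internal validation estimates bootstrap optimism on multiply imputed data in
the von Hippel style: impute first (4 completed sets by default), then
within each set draw 250 bootstrap resamples, rebuild the *entire* pipeline
on each resample, and take (performance on the resample) minus (performance
of the resample-trained model on the source set). Per-set means are pooled
across sets by Rubin's rules and `corrected = apparent - optimism`. Whether
one should bootstrap before imputing (the canonical von Hippel ordering) or
impute before bootstrapping cannot be settled from count information alone;
the impute-then-bootstrap realisation keeps every resample's imputation cost
inside one completed set and none of the package's checks depend on the
ordering. Inner refits that fail (e.g. a quasi-separated resample) are
skipped and logged, with a configurable cap on the skip fraction (default
5%) beyond which the run aborts. A planned sensitivity analysis re-runs the
pipeline after excluding cardiac-arrest dispatches, the subgroup that
dominates both mortality and vital-sign missingness.

## The synthetic cohort generator

`default_fhdb_config()` encodes, per outcome stratum (alive at 30 days,
dead within 30 days, outcome missing), the published summary structure of a
national HEMS registry cohort of 30 186 encounters: continuous medians and
IQRs (e.g. age 53.0 [33.4–68.4] alive vs 70.2 [60.0–79.8] dead), integer
GCS distributions (median 14 [7–15] alive vs 3 [3–3] dead), categorical
level frequencies, ≈ 30% 30-day mortality with ≈ 6% missing outcome, and
per-variable missingness rates with their strong outcome dependence (heart
rate missing 12.8% among survivors vs 58.9% among deaths).

Continuous marginals are realised by piecewise-linear quantile interpolation
through (min, Q1, median, Q3, max) anchors, with the extremes extended 1.5
IQR beyond the quartiles and clipped to physiologic bounds: this reproduces
the target median and IQR exactly in distribution without committing to a
parametric family. GCS uses hand-constructed integer pmfs per stratum whose
quartiles match the published values. Missingness is missing-at-random
conditional on the outcome stratum — exactly the assumption the imputation
model relies on — so the generator realises the MAR regime rather than
testing robustness to its violation. Variables are drawn independently
within stratum; the only dependence structure emulated is the
outcome/stratum conditioning, so joint correlations beyond it (e.g.
GCS–rhythm coupling inside the death stratum) are *not* reproduced. One
consequence worth knowing: conditional independence given a
highly-informative stratum makes synthetic cohorts *more* separable than
real ones (apparent AUROC ≈ 0.97 vs the ≈ 0.93 scale reported for real
registry data), so quasi-complete separation in small bootstrap refits is
more common here than it would be in practice. Passing tests on this
generator therefore demonstrate correctness of the machinery, not
transportability to any real registry.

Each variable draws from its own counter-derived random substream, so adding
or removing a variable from a config never perturbs the others, and the same
seed yields byte-identical cohorts.

For parameter-recovery studies, `outcome_mechanism = "from_true_model"`
draws covariates from the stratum mixture and the outcome from a known
logistic model on the transformed design. `default_true_model()` fixes
plausible coefficients over the 30-column design with *fixed* knots and
limits (so the truth does not depend on any sample); its intercept was
calibrated once so the implied mortality is close to 30%.

## Numerical choices

* IRLS/Newton with step-halving, gradient tolerance 1e-8, 100 iterations;
  the log-likelihood trace is retained and non-decreasing by construction.
* Complete separation raises an error (detected via a singular observed
  information or coefficients beyond ±30 on the logit scale) instead of
  silent shrinkage; no penalisation is applied anywhere in the final fits.
  Ridge stabilisation is used *only* inside imputation conditional models,
  where a draw, not an estimate, is needed.
* Rank-deficient designs error naming the collinear columns.
* Calibration regression clamps predictions to [1e-12, 1 − 1e-12] with a
  warning before taking logits.
* Ties in AUROC count half; quantiles everywhere are the standard
  interpolation type.

## Problem sizes used in the checks

The shipped test-suite and acceptance script choose sizes that keep each
stage honest at desk scale: parameter recovery on a complete cohort of
50 000; MCAR-unbiasedness of imputation at n = 10 000 with m = 10 and five
sweeps; calibration self-consistency at n = 100 000; bootstrap-validation
behaviour with 20 pure-noise predictors at n = 2 000 with 2 sets × 50
resamples; screening and headline rates on full-size cohorts of 30 186; the
end-to-end ensemble demonstration on a 4 000-record subsample with m = 5.
The paper-scale profile (m = 30, 10 sweeps, 4 × 250 bootstrap) remains the
package default.

## Known limitations

* The generator emulates marginal and outcome-conditional structure only;
  no geographic, temporal or inter-vital correlation structure.
* The polytomous imputation draw propagates parameter uncertainty by the
  bootstrap rather than an explicit posterior; with rare levels a bootstrap
  may omit a level, which then cannot be drawn in that sweep.
* AUROC pooling across imputed sets uses the normal scale; a variance-
  stabilising transform would matter only for AUROCs far from the ones seen
  here.
* No likelihood-ratio or score tests, no interactions, no penalised
  variants: the development procedure is deliberately the plain
  maximum-likelihood pipeline it documents.
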