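# champr

Development and internal validation of missingness-adaptive 30-day
mortality prediction algorithms for pre-hospital critical care (HEMS)
cohorts.

## The problem

Intensive care has severity-of-illness scores (APACHE, SAPS) that let units
compute standardised mortality ratios for audit and benchmarking. No
comparable tool existed for the patients attended by physician-staffed
helicopter emergency medical services — a population in which missing data
is not an accident but a structural feature: vital signs are unmeasurable in
cardiac arrest, and the sickest patients have the most missing values.

`champr` implements the CHAMP (Critical HEMS Algorithm for Mortality
Prediction) methodology end-to-end:

1. **Screening** of 14 candidate predictors: drop a variable above 1/3
   missingness, drop levels below 2% prevalence, merge levels with under 2%
   mortality into the reference group — leaving 11 predictors.
2. **Multiple imputation by chained equations** (predictive mean matching,
   logistic and polytomous draws; default 30 completed datasets × 10
   sweeps), with estimates pooled by Rubin's rules.
3. **Winsorized spline logistic models**: continuous predictors winsorized
   1% at both ends (GCS exempt) and expanded in restricted cubic splines —
   three knots for GCS, four for the rest. For knots `t_1 < … < t_k` the
   non-linear basis terms are

   ```
   B_j(x) = [ (x−t_j)₊³ − (x−t_{k−1})₊³ (t_k−t_j)/(t_k−t_{k−1})
                        + (x−t_k)₊³ (t_{k−1}−t_j)/(t_k−t_{k−1}) ] / (t_k−t_1)²
   ```

   linear beyond the boundary knots. Inference is by block Wald tests.
4. **A 32-model ensemble**: one submodel per subset of the five predictors
   with the most missing data (systolic blood pressure, heart rate, oxygen
   saturation, GCS, arrest-rhythm indicator). Scoring selects the submodel
   matching each record's availability pattern, so every observed variable
   is used and no missing one is. The bank exports to a versioned JSON
   registry for standalone scoring.
5. **Performance and internal validation**: AUROC (DeLong CI), Brier score,
   calibration slope and calibration-in-the-large intercept,
   Hosmer–Lemeshow, GAM calibration curve; bootstrap optimism in the
   von Hippel style (impute, then bootstrap within completed sets, pool
   across sets), with `corrected = apparent − optimism`; and a sensitivity
   analysis excluding cardiac-arrest dispatches.

Because the source registry is not public, the package ships a synthetic
cohort generator calibrated to the published population characteristics
(per-outcome-stratum medians/IQRs, level frequencies, outcome-dependent
missingness, ≈30% mortality), with an optional known logistic ground truth
for parameter-recovery studies. See `vignette("champ-methods")` for the full
methods account.

## Worked example

```r
library(champr)

sim    <- generate_cohort(default_fhdb_config(n = 5000, seed = 1))
cohort <- sim$observed

screen_variables(cohort)
#> Predictor screening
#>   retained (11): sbp, heart_rate, spo2, gcs, sex, age, vehicle, facility, rhythm_binary, time_to_hems, category
#>   dropped:
#>     resp_rate    missing_fraction (0.459)
#>     time_to_ems  missing_fraction (0.655)
#>     n_patients   rare_level (0.017)
#>   merged category levels -> infection_or_gyn_obstetrics: gyn_obstetrics, infection
```

Respiratory rate and time to first-EMS arrival exceed the 1/3 missingness
cut-off, multi-patient missions are too rare (1.7% < 2%), and the infection
and gynaecology/obstetrics categories merge into the reference group —
reproducing the published selection. Development, scoring and apparent
performance:

```r
dev <- champ_develop(cohort, m = 5, maxit = 3, seed = 1)
dev$ensemble
#> Pattern-submodel ensemble: 32 models over 5 droppable predictor(s)
#>   droppable (mask order): sbp, heart_rate, spo2, gcs, rhythm_binary
#>   pooled over m = 5 imputation(s), n = 5000

dev$performance
#> Performance report (n = 4710, event rate 30.6%)
#>   AUROC     0.971 (0.967 to 0.976)
#>   Brier     0.057
#>   Slope     1.027 (0.963 to 1.092)
#>   Intercept -0.006 (-0.124 to 0.111)
#>   Hosmer-Lemeshow chi2 = 5.1 on 8 df (p = 0.749)
```

The ensemble scores every record with the most informative applicable
submodel (290 of the 5000 records here lack the outcome or a required core
variable and are excluded with explicit reasons). Pooled odds ratios from
the full model behave as the clinical picture demands — arrest rhythm
dominates:

```r
odds_ratios(dev$ensemble$models[["11111"]],
            c("rhythm_binary", "sex_male", "facility_yes"))
#>            term estimate conf.low conf.high
#> 1 rhythm_binary    37.42    25.62     54.67
#> 2      sex_male     1.65     1.25      2.18
#> 3  facility_yes     2.83     1.78      4.52
```

(Synthetic cohorts draw variables independently within outcome stratum, so
they are *more* separable than real registry data — apparent AUROC ≈ 0.97
here vs the ≈ 0.93 scale typical of the real cohort.)

Registries round-trip for standalone scoring:

```r
export_registry(dev$ensemble, "registry.json")
champ_score(import_registry("registry.json"), cohort)
```

A thin CLI over the same functions lives in `inst/scripts/champ`
(`simulate`, `screen`, `develop`, `score`, `validate` subcommands).

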