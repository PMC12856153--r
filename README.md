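# le8af

Cardiovascular health and prognosis in atrial fibrillation: an R package
implementing the full analytical chain for studying the American Heart
Association's **Life's Essential 8 (LE8)** score as a prognostic marker in
people with AF, together with a calibrated synthetic-cohort generator so
the whole study runs without access-restricted data.

**Who it is for.** Cardiovascular epidemiologists and biostatisticians who
want a reproducible, tested implementation of: LE8 scoring from raw
measurements, ICD-10-based endpoint derivation, penalised-spline Cox
modelling of a continuous exposure, and scenario-based attributable /
impact fractions — either to reanalyse their own cohort tables or to study
the methodology on simulated data.

## The model

For participant *i* with composite score `LE8_i` (the mean of eight 0–100
component scores), outcomes over a 10-year horizon follow a proportional
hazards model

```
h_i(t) = h0(t) · exp( f(LE8_i) + γ'z_i )
```

where `f` is a penalised cubic B-spline with 4 effective degrees of
freedom fixed a priori and `z_i` are adjustment covariates (Model 1: none;
Model 2: age, sex, Townsend deprivation; Model 3: + six comorbidities).
Quartile hazard ratios use Q1 (least healthy) as reference. From the
fitted curve `HR(x) = exp(f(x) − f(ref))` the package computes

```
PAF = 1 − n·HR(x_ref) / Σ HR(x_i)                (population attributable fraction)
PIF = 1 − Σ HR(x'_i) / Σ HR(x_i),  x' = min(x+20, 100) for x < 50
```

plus per-component impact fractions (one component improved by 20 points
among those below its eligibility threshold, composite recomputed),
bootstrap percentile intervals, Schoenfeld diagnostics, spline-by-moderator
likelihood-ratio moderation tests, a 2-year landmark reanalysis, and a
Fine–Gray competing-risk model for MACE. Crude event rates per 1000
person-years carry log-scale Poisson normal-approximation intervals.

## Worked example

```r
library(le8af)
spec   <- cohort_spec(n_participants = 10000, seed = 42)
cohort <- generate_cohort(spec)          # synthetic AF cohort + ICD-10 stream
scored <- cohort$scored                  # LE8 components, composite, quartile
rec    <- derive_survival(cohort$participants, cohort$diagnoses,
                          mortality_endpoint())
d      <- survival_dataset(rec, cohort$participants, scored)

rate_table(rec, d$quartile)[, c("group","events","rate_rounded",
                                "ci_low_rounded","ci_high_rounded")]
#>   group events rate_rounded ci_low_rounded ci_high_rounded
#> 1    Q1    658           46             43              50
#> 2    Q2    470           32             29              35
#> 3    Q3    377           25             23              28
#> 4    Q4    317           21             18              23

fit_cox(d, exposure_form = "quartile", adjustment = "model3")
#> Cox model (model3, quartile exposure), 1822 events
#>          term   coef    se    hr ci_low ci_high p
#> 1  quartileQ2 -0.329 0.062 0.720  0.637   0.812 0
#> 2  quartileQ3 -0.550 0.068 0.577  0.505   0.659 0
#> 3  quartileQ4 -0.744 0.072 0.475  0.412   0.548 0
#> ...

fs <- fit_cox_pspline(d, adjustment = "model3")
fs
#> Penalised-spline Cox model (model3), 1822 events
#>   effective df: 4.07
#>   linear trend: beta = -0.02335 , SE = 0.0018 , p = <2e-16

pif(fs, d$le8, shift_points = 20, eligibility_threshold = 50,
    boot_reps = 200)
#> PIF = 0.0544 (95% CI 0.050-0.058)  [n eligible: 766]
#>   scenario: +20 points for exposure < 50 (cap 100)
```

Reading: crude mortality falls monotonically across LE8 quartiles (46 →
21 per 1000 person-years); after full adjustment the healthiest quartile
has roughly half the hazard of the least healthy (HR 0.48); the spline's
linear trend is −0.023 log-hazard per LE8 point; and a +20-point
improvement for everyone scoring below 50 would, under the scenario's
causal assumptions, avert about 5 % of deaths.

The complete study — simulation at n = 23,758, scoring, rates and KM
curves, Models 1–3, diagnostics, moderation, PAF/PIF with bootstrap CIs,
landmark and competing-risk sensitivity analyses — is organised as
numbered drivers:

```sh
Rscript analysis/01_simulate.R    # cohort CSVs under results/study/
Rscript analysis/02_score.R
Rscript analysis/03_outcomes.R
Rscript analysis/04_cox_models.R
Rscript analysis/05_impact.R
Rscript analysis/06_sensitivity.R
```

or as one call, `run_pipeline(pipeline_config(out_dir = "results/run"))`,
which also writes a config-hash manifest. The methods vignette
(`vignettes/le8af-methods.Rmd`) documents the model, the generator's
calibration, and every numerical choice.

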