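---
title: "Methods: cardiovascular health scoring, spline Cox models and impact fractions in atrial fibrillation"
author: "le8af"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: cardiovascular health scoring, spline Cox models and impact fractions in atrial fibrillation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The question the package addresses

People with atrial fibrillation (AF) carry high risks of death and of major
adverse cardiovascular events (MACE). The package studies whether composite
cardiovascular health — the American Heart Association's Life's Essential 8
(LE8) score, the mean of eight 0–100 component scores for diet, physical
activity, smoking, sleep, BMI, non-HDL cholesterol, blood glucose and blood
pressure — predicts 10-year outcomes in an AF population, and how much of
the event load could hypothetically be removed by improving cardiovascular
health. The real cohort this design targets (UK Biobank participants with
ICD-10 code I48 before baseline) is access-restricted, so the package pairs
the analysis chain with a calibrated synthetic-cohort generator: every
stage is runnable, testable and reproducible without restricted data.

## LE8 scoring

Component scores are piecewise-constant band lookups shipped as a versioned
plain-text table (`inst/extdata/le8_rubric_v1.csv`), following the
published AHA rubric: e.g. BMI < 25 kg/m² scores 100, 25–29.9 scores 70,
and so on; never smokers score 100, current smokers 0, former smokers 25–75
by years since quitting. Two adaptations reflect the data the design
assumes:

* **Physical activity** arrives as MET-min/week (IPAQ-style), so the AHA
  minute bands are expressed in MET-minutes at a moderate-intensity
  equivalent of 4 MET (150 min/week ⇔ 600 MET-min/week).
* **Diet** is an adapted nine-item score (processed meat, red meat, fish,
  alcohol, spread type, wholegrain cereal, salt use, water, fruit and
  vegetables, each pre-coded as met/not met). The count of items met is
  ranked against the cohort and the cohort quartile mapped to
  {0, 100/3, 200/3, 100}. The exact per-item healthy criteria are applied
  upstream of the package (the generator emits binary indicators); the
  mapping to points is the package's contract. Alternative point mappings
  can be supplied by editing the rubric file.

Treatment modifiers follow the AHA rubric where it defines them:
antihypertensive use deducts 20 blood-pressure points and lipid-lowering
use 20 lipid points (floored at zero); diagnosed diabetes (or HbA1c ≥ 48
mmol/mol) caps the glycaemia score at 40 and grades it down by control.
Whether the source analysis applied these deductions is not stated in its
methods; we adopt the rubric as published and note that the package's
conclusions about component rankings are robust to this choice in the
calibrated cohort.

The composite is the unweighted mean of the eight components. Cohort
quartiles cut at the empirical 25/50/75th percentiles; tied boundary values
go to the lower quartile, and with all-distinct values group sizes follow
the largest-remainder rule (extra members to the lowest quartiles), so
23,758 distinct scores split 5940/5940/5939/5939. Q1 is the least healthy
quartile and serves as the Cox reference.

## Outcomes

All-cause mortality comes from death dates; MACE is the first
post-baseline occurrence of ischaemic heart disease (I20–I25), myocardial
infarction (I21–I23), stroke (I60, I61, I63, I64) or heart failure (I50.0,
I50.1, I50.9). Range patterns include all decimal children; enumerated
decimal codes match exactly. Qualifying codes dated at or before baseline
are prevalent disease: they never count as outcome events (their count is
reported), but the participant remains in follow-up — prior disease is
handled as adjustment covariates, not exclusion. Follow-up is truncated at
10 years; person-years are capped there. For MACE, death without a prior
MACE is kept as a distinct `competing_death` state so the cause-specific
and subdistribution analyses can share one dataset.

Crude rates are events per 1000 person-years. The 95 % interval uses the
normal approximation to the **log** Poisson rate,
`rate × exp(±1.96/√events)`. We chose this form because the printed
intervals of the tables the package reproduces discriminate between
candidate methods: the count-scale normal approximation fails one of the
eight cells (it gives an upper bound of 48 where 49 is printed), while the
log-scale form reproduces all eight pairs under half-up integer rounding.
Count-scale normal and exact Garwood (chi-square) intervals remain
available via `method =`.

## Cox models

All fits use the partial likelihood with Efron tie handling (the source
analysis does not state its tie method; Breslow is selectable, and the two
coincide when event times are distinct). Three adjustment sets mirror the
study design: Model 1 unadjusted; Model 2 age, sex, Townsend deprivation
index; Model 3 additionally six baseline comorbidities (stroke, MI,
chronic coronary syndrome, heart failure, type-2 diabetes, depression).
Multimorbidity means ≥ 1 of those six.

The continuous LE8 effect is modelled with a penalised cubic B-spline
(`survival::pspline`) whose smoothing parameter is searched so the
effective degrees of freedom hit 4, fixed a priori; the search tolerance
is the pspline default (±0.1 df) and the spline basis uses equally spaced
knots (`nterm = 8`), the behaviour of the implementation the source
analysis itself used. The reported "linear trend" of a spline fit is the
information-weighted projection of the spline coefficients onto the basis
centres — exactly the decomposition `survival` prints as the linear term —
with its delta-method standard error. As the smoothing parameter
saturates, the second-difference penalty forces the curve into its null
space (a linear function), so the spline fit collapses onto the linear
Cox coefficient; the tests verify this limit to 1e-3.

Hazard-ratio curves are `HR(x) = exp(f(x) − f(ref))` with pointwise
delta-method intervals from the basis-contrast covariance. The default
reference is the sample median LE8 (the source does not state its
reference; it is configurable), so `HR(ref) = 1` exactly. Grid points
outside the observed range are clipped with a warning rather than
extrapolated.

Moderation by age group (dichotomised at 60), sex and multimorbidity is
tested on the multiplicative scale: the spline-plus-moderator model is
compared against the model additionally allowing the LE8 trend to differ
by moderator level (explicit trend-by-level product columns), via a
likelihood-ratio test. The chi-square df is the difference in total
effective degrees of freedom, rounded — approximate, as is standard for
penalised fits. Proportional hazards are checked with scaled Schoenfeld
residual score tests (`survival::cox.zph`).

Sensitivity analyses: (1) a 2-year landmark reanalysis removing every
record that ends (event or censoring) at or before 2 years; survivors keep
the original time origin with delayed entry at the landmark, since
re-zeroing is not stated in the source design; (2) a Fine–Gray
subdistribution-hazard model for MACE via censoring-distribution-weighted
risk sets (`survival::finegray` + weighted Cox), which provably reduces to
the cause-specific model when no competing events exist — a tested
contract.

## Attributable and impact fractions

With `HR(x)` the fitted Model-3 curve, the package computes

* `PAF = 1 − n·HR(x_ref) / Σ HR(x_i)` — the fraction of events removed if
  everyone sat at a reference exposure. The default reference rule is the
  minimum-hazard point of the fitted curve within the observed range
  (alternatives: score 100 clipped to range; the mean of the healthiest
  quartile). The source analysis does not state its rule, so sensitivity
  across rules is one function argument away.
* `PIF = 1 − Σ HR(x′_i) / Σ HR(x_i)` with `x′ = min(x + 20, 100)` for
  everyone below 50 points — the +20-point targeted-intervention scenario.
* Component PIFs: one component score is raised 20 points (capped at 100)
  for participants below that component's eligibility threshold (< 50 for
  smoking, diet, blood pressure; < 60 for non-HDL and HbA1c; < 70 for BMI,
  activity, sleep), the composite is recomputed as the mean of eight (so
  it rises by at most 2.5 points), and the PIF is evaluated through the
  composite curve. Fitting eight separate component–outcome curves would
  be the alternative pathway; we use the composite curve because the
  scenario is defined as an increase *in the LE8 score*, and note the
  choice is not identifiable from published magnitudes alone.

Confidence intervals are nonparametric bootstrap percentiles (500
replicates, fixed seed). Replicates can refit the spline
(`impact_bootstrap`, reflecting curve uncertainty) or resample exposures
against the fixed curve (fast mode; the pipeline default). Degenerate
replicates are dropped and counted. All impact outputs carry an explicit
caveat string: these are hypothetical, scenario-based measures assuming a
causal association, exposure stability and no residual confounding.

## The synthetic cohort generator

The generator is first-class, tested code — it defines the study
conditions for every downstream check. One latent "healthiness" factor
`h ~ N(0,1)` per participant induces the correlation among components.
Each raw measurement is drawn around a piecewise-linear interpolation (in
`h`, with knots at the standard-normal quartile midpoints) of a
per-quartile target profile: means/SDs of age, Townsend, BMI, SBP/DBP
(bivariate, ρ = 0.6), lognormal MET-min/week, and HbA1c as a
non-diabetic/diabetic mixture; categorical gradients (sex, smoking
ordered categories, medications, comorbidities) interpolate on the logit
scale. The default profile encodes the published baseline table of the
emulated AF cohort (n = 23,758, mean age 61.82, SD 6.1, 33 % female,
quartile-graded BMI/BP/activity/smoking/HbA1c). Sleep, per-item diet
prevalences and comorbidity gradients are not tabulated there; defaults
are field-typical values chosen once (sleep ≈ 7.1 ± 1.1 h with a mild
gradient; diet-item logits spread so items-met spans ≈ 2.7–6.4 across the
health range; comorbidity prevalences declining with health).

Because cohort quartiles are formed on the *scored* composite, adjacent
latent classes mix at the boundaries and the observed per-quartile
gradient is compressed (or, where a high-variance component feeds
selection, stretched) relative to the latent profile. The generator
therefore adds small fixed offsets to four latent mean profiles (BMI,
SBP, DBP, MET), obtained once by damped fixed-point iteration at
n = 100,000, so that the *scored-quartile* summaries land on the targets;
the tests verify BMI, SBP and MET-min quartile means within 5 % at
n = 20,000. Two deliberate departures from naive baseline-table
arithmetic: non-HDL cholesterol is drawn as a statin-era,
treated-to-target distribution (means ≈ 3.1–3.25 mmol/L, treated −0.7),
because the published component-impact pattern is only reproducible when
almost nobody scores below the lipid eligibility threshold; and
non-diabetic HbA1c means are back-computed so the diabetic/non-diabetic
mixture hits the published per-quartile HbA1c means.

Survival is simulated by inverse transform under proportional hazards:
hazard `λ₀ · exp(β · (LE8 − 65))` with β = −0.025 per point for death and
−0.018 for MACE (the fully adjusted slopes of the emulated analysis),
exponential by default (Weibull shape configurable — the source states no
baseline form), independent exponential censoring, and administrative
censoring at 10 years. The default baseline hazards (0.033/y death,
0.05/y MACE) and censoring rate (0.085/y) were chosen once so that
overall person-time and crude event fractions match the published tables
(≈ 5.9 person-years/participant and ≈ 19 % deaths; ≈ 4.9 and ≈ 24 % for
MACE). Observed MACE diagnoses are emitted as ICD-10 codes only while the
participant is alive, linked and inside the horizon; comorbidity flags
emit prevalent codes at day ≤ 0, and every participant carries I48 at or
before baseline. Unrelated noise codes exercise the endpoint filter.

Determinism: one master seed fills an n × 40 uniform matrix, one row per
participant, and every draw is an inverse-CDF transform of that row — so
the same (spec, seed) regenerates an identical cohort, and raw records
are prefix-stable as n grows (the diet quartile reference and hence
survival draws may shift slightly with n, since diet is cohort-relative).

What the generator does *not* emulate: recruitment and sampling bias,
missingness (complete cases by construction; the scorer's complete-case
rule is still enforced and logged), measurement error in self-reported
behaviours, time-varying exposures, effect heterogeneity (the default
effect is homogeneous, so moderation tests are expectedly null on default
cohorts — the moderation machinery is validated in tests on explicitly
heterogeneous simulations), and any real linkage formats. Passing tests
on synthetic cohorts therefore demonstrate correctness of the analysis
machinery under the stated data-generating assumptions, not real-data
validity.

## Numerical choices and degenerate inputs

* Half-up rounding (`round_half_up`) for published-style integer rates.
* All-identical composites: quartile assignment degenerates to Q1 with a
  warning; a zero-spread diet distribution falls back to absolute bands
  0–2/3–4/5–6/7–9 with a warning.
* Zero events in a rate group: rate 0 with a degenerate (0, 0) interval
  and a warning; zero person-years is an error.
* Rank-deficient or constant design columns are rejected before fitting;
  suspected separation (non-finite coefficients or exploding SEs) raises
  a divergence error; non-convergence is an explicit `converged = FALSE`
  state.
* A moderator level without events is a stratum error; an empty cohort is
  a size error; reference exposures outside the fitted support are rule
  errors.
* Spline df search failing to reach the target within ±0.15 raises a spec
  error suggesting more knots.

## Problem sizes

The test suite exercises the full chain at n = 1,500–20,000 (parameter
recovery runs 50 replicates at n = 20,000; oracle checks use exhaustive
small cases), chosen to keep Monte-Carlo error well below the asserted
tolerances while the whole suite runs in about a minute. The analysis
scripts and the acceptance script run the complete study at the published
cohort size, n = 23,758, with 500 bootstrap replicates in fast mode.

## Known limitations

PAF/PIF magnitudes depend on the composite's distribution (especially the
fraction below 50 points), which the published baseline table only
partially constrains; on synthetic cohorts they land in the published
order of magnitude but are not numeric reproductions. The moderation df
convention for penalised fits is approximate. The equal weighting of the
eight components is inherited from the LE8 definition itself; nothing in
the package reweights them.
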