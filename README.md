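# dietrisk

Nonlinear diet–mortality dose–response analysis for longitudinal dialysis
cohorts.

## The problem

Dietary management is central to the care of end-stage renal disease
patients on peritoneal dialysis, yet intake guidance for many nutrients is
extrapolated from the general population, and the relationship between a
nutrient's intake and mortality is often not monotone: both deficient and
excessive intake can be harmful. Conventional per-nutrient Cox regression
reports a single hazard ratio per nutrient and, by construction, cannot
express a U-shaped risk profile — a strongly U-shaped nutrient can look
"null" in a linear model.

`dietrisk` is for biostatisticians and nutritional epidemiologists who want
to estimate, from longitudinal cohort data (repeated clinic visits with lab
panels, repeated dietary records, and a survival outcome), the intake range
of each nutrient associated with below-average mortality hazard, stratified
by baseline serum-albumin tertile.

## The method

For patient *i* with time-averaged nutrient intake *x*ᵢ and confounders
**z**ᵢ, the package fits, per nutrient and patient group:

**Stage 1 — risk scoring.** A multivariate Cox proportional-hazards model
(Efron tie handling)

> h(t | xᵢ, **z**ᵢ) = h₀(t) · exp{ Σⱼ θⱼ Cⱼ(xᵢ) + **γ**ᵀ**z**ᵢ }

where C₁,…,C_{k−1} is a restricted cubic spline basis of intake (knots at
Harrell's percentiles; linear beyond the boundary knots) and **z** is the
19-variable confounder set (serum chemistry, vitals, diabetes, BMI, GFR).
Each patient's linear predictor ηᵢ becomes a dietary risk score
sᵢ = exp(ηᵢ − mean η), with geometric mean 1.

**Stage 2 — dose–response extraction.** Ordinary least squares of log sᵢ on
the same spline basis of intake gives the fitted log-hazard-ratio curve
ĝ(x); nested F-tests give an overall *P* (spline vs. intercept) and a
nonlinearity *P*-NL (spline vs. straight line). After centring ĝ to mean
zero over the group's empirical intake distribution, the protective set
{x : exp(ĝ(x)) < 1} is reported as points **A**, **B**, **C** — the ranges
[A, B] and optionally [C, max) where estimated hazard falls below the
group's average.

Around this core the package provides: a two-level time-averaging
preprocessor (fixed 6-month windows anchored at each patient's entry, then
an unweighted mean across windows) with last-observation-carried-forward
lab imputation; ideal-body-weight (height − 105 cm) normalisation for DPI
and DEI; albumin-tertile stratification with the standard descriptive
battery (ANOVA + Tukey HSD, chi-square, Kaplan–Meier, log-rank); a
reproducible synthetic-cohort generator with known ground-truth effects;
and the published result tables as machine-readable fixtures.

## Worked example

```r
library(dietrisk)

# a synthetic 400-patient cohort in which zinc truly has a U-shaped effect
cfg <- cohort_config(
  n_patients = 400, seed = 42,
  effect_specs = list(effect_spec("zn", "quadratic",
                                  center = 8.18, curvature = 0.06)))
cohort <- generate_cohort(cfg)
cohort
#> <diet_cohort> 400 patients, 6011 visits, 4810 diet records, 239 deaths

profiles <- build_profiles(cohort)          # time-averaged, one row/patient
groups   <- tertile_split(profiles$baseline_albumin, profiles$patient_id)
attr(groups, "cutpoints")
#> [1] 34.99773 39.26986

fit <- diet_response(profiles, "zn")
summary(fit)
#> Nutrient zn, group all: n = 396, deaths = 235
#>   Linear Cox HR per 1 unit: 1.054 (95% CI 0.996-1.115), p = 0.0704
#>   Spline: knots at 3.699, 7.126, 9.365, 13.11
#>   P = 2.91e-104, P-NL = 1.12e-103; protective points A = 5.34, B = 10.65, C = -

cohort$truth$protective_intervals[[1]]$interval   # analytic ground truth
#> [1]  5.338297 11.021703
```

The conventional linear Cox model sees nothing (HR 1.05, *P* = 0.07): the
U-shape averages out. The two-stage fit flags decisive nonlinearity and
recovers the analytic protective interval (5.34, 11.02) as [5.34, 10.65] —
intakes in that range carry below-average estimated hazard. `plot(fit)`
draws the centred hazard-ratio curve with its 95% band, the HR = 1
reference line and the shaded protective range;
`range_table(profiles, groups)` assembles the A/B/C report across all
nutrients and albumin strata, and `hr_table()` its linear-HR companion.

`run_pipeline()` drives the whole chain (simulate → preprocess → stratify →
stage 1 → stage 2 → reports) from one configuration list and writes CSV
tables plus a JSON manifest.

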