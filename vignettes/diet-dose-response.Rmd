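---
title: "Estimating protective nutrient intake ranges with a two-stage Cox/spline model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating protective nutrient intake ranges with a two-stage Cox/spline model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

```{r setup}
library(dietrisk)
```

## The estimand

For one nutrient and one group of patients, the target is the set of daily
intake levels associated with below-average mortality hazard, after
adjustment for the patient's clinical state. Writing the adjusted
log-hazard contribution of intake as g(x), the protective set is
{x : exp(g(x) − ḡ) < 1}, where ḡ is the mean of g over the group's intake
distribution — i.e. intakes whose estimated hazard sits below the group
average. The set is reported as up to three points: [A, B], optionally
plus [C, max observed intake]. For a U-shaped g this is a single finite
interval; for a monotone protective effect it is a half-line (B absent).

## The two-stage model

**Stage 1.** A multivariate Cox proportional-hazards model of all-cause
mortality with the Efron correction for tied event times. The nutrient
enters through a restricted cubic spline basis (default) so the hazard may
depend on intake nonlinearly; the 19 confounders (serum chloride, CO2
combining power, white cells, hemoglobin, urea, serum calcium, potassium,
sodium, creatinine, phosphorus, albumin, hs-CRP, glucose, weight, systolic
and diastolic pressure, diabetes, BMI, GFR) enter linearly. Each patient's
full linear predictor η is turned into a risk score s = exp(η − mean η),
normalised so the geometric mean is exactly 1: s below 1 means "predicted
risk below the group average".

A design point worth making explicit: the per-nutrient hazard-ratio table
(`nutrient_hr()`, `hr_table()`) uses a strictly linear nutrient term,
because a single HR per scaled unit is what such tables mean. The scoring
model behind stage 2, however, must let the nutrient bend. If the score
came from the linear-nutrient model, log s would be exactly linear in
(x, z), so its conditional expectation given intake would be a straight
line whenever intake and confounders are jointly linearly related — no
second stage could then see curvature, and a U-shaped nutrient would be
invisible by construction. `diet_response()` therefore scores from the
spline-expanded Cox model; `nutrient_form = "linear"` is available for the
monotone-threshold reading, without any claim that it can detect
nonlinearity.

**Stage 2.** Ordinary least squares of log s on the same spline basis of
intake. Because log s is the Cox curve plus the confounder part of the
linear predictor, this regression re-estimates the dose-response curve and
propagates confounder variation into honest residual noise. Two nested
F-tests follow: overall P (spline vs intercept-only) and nonlinearity P-NL
(spline vs straight line). The fitted curve, centred to mean zero over the
group's observed intakes — the same reference as the score centring, so
both stages share one "HR = 1" — is evaluated on a 200-point grid and its
sub-unity region is decomposed into the reported A/B/C points.

Assumptions inherited from the components: proportional hazards and
non-informative censoring (Cox), correct confounder set (no unmeasured
confounding), and enough intake support to place spline knots.

## Spline and numerical choices

* **Basis.** Harrell's truncated-power restricted cubic form, normalised
  by (t_k − t_1)²; continuous second derivatives, exactly linear outside
  the boundary knots. A consequence used by the tests: fitting an exactly
  linear target returns zero nonlinear coefficients (to 1e-8), and the
  fitted curve's second differences vanish beyond the boundary knots.
* **Knots.** Default k = 4 at the 5th/35th/65th/95th intake percentiles
  (10/50/90 for k = 3; 5/27.5/50/72.5/95 for k = 5) — the standard choice
  for cohorts of a few hundred. If ties make those non-increasing, equally
  spaced quantiles are used; fewer than 10 distinct intakes is an error.
* **Range extraction.** Crossings of the centred curve with zero are
  located by linear interpolation between adjacent grid nodes; protective
  components narrower than 2% of the observed domain are suppressed as
  grid noise; if more than two components survive, the two widest are kept
  with a warning (the reported shape never needs more than three points).
  An everywhere-nonnegative curve yields an empty report rather than an
  error.
* **Cox fitting.** Delegated to `survival::coxph` (Efron ties); the
  wrapper enforces this package's contracts (at least one event, finite
  covariates, no constant column) and surfaces convergence failure as an
  error naming the problem. Its correctness is cross-checked in the test
  suite against a hand-written brute-force partial-likelihood grid search
  on small instances, and against a single-stage spline-in-Cox fit at the
  interval level.
* **Degenerate descriptive inputs.** All-equal albumin values collapse the
  tertile split to "medium" with a warning; zero-variance group
  comparisons report P = 1 with a warning; empty groups are dropped from
  the log-rank test with a warning.
* **Significance conventions.** 0.05 two-tailed throughout, no
  multiple-testing correction across nutrients or variables (a deliberate
  mirror of descriptive practice in this literature; treat the tables as
  exploratory). For the printed-table counting utilities both threshold
  conventions are explicit flags, because printed tables are internally
  inconsistent about cells lying exactly at 0.05: `count_significant()`
  defaults to inclusive (a printed "0.05" counts), while
  `count_joint_significant()` defaults to strict.

## Preprocessing

Follow-up is cut into half-open windows [0, w), [w, 2w), … of
`window_length` = 6 months, anchored at each patient's own entry (the
scheme is defined relative to follow-up start, not calendar time). Within
a window, records are averaged; the patient's exposure is then the
unweighted mean of window means. This two-level average deliberately
differs from the pooled mean — a densely sampled sick spell should not
dominate the exposure estimate; the documented toy case {10, 20 | 30}
gives 22.5, not 20. Windows with no records are dropped, not zero-filled.

Lab values are imputed by last observation carried forward *within
patient, labs only*: dietary records have no within-record missingness, so
an absent diet record simply contributes nothing to its window. Values
before a patient's first observation stay missing. Ideal body weight is
height (cm) − 105 (modified Broca); DPI and DEI are the time-averaged
protein (g/d) and energy (kcal/d) divided by it. Patients with no diet
record, no visit, or height ≤ 105 cm are excluded with a recorded reason
rather than failing the batch.

Baseline tables use each patient's entry values (first visit), matching
the convention that initial-visit results serve as baseline.

## What the synthetic generator emulates

`generate_cohort()` draws a cohort whose scale mirrors a real
peritoneal-dialysis registry: 26-nutrient dietary records (24 recorded
intakes; DPI/DEI derived at preprocessing) with marginals set to the
cohort-level means/SDs of the time-averaged intake table; a 17-feature lab
panel with the published per-feature missingness (6–29%, e.g. albumin 22%,
hs-CRP 29%); whole diet records missing at 20%; quarterly-ish visits
(renewal intervals ~ Normal(3, 1) months, truncated at 0.5); a 144-month
administrative horizon.

One latent "health" factor per patient links everything: it loads on the
labs (0.6 on albumin, 0.3 elsewhere), on nutrient intake (0.3), and —
through the lab coefficients on the hazard (−0.04 per g/l centred albumin,
−0.004 per g/l hemoglobin, +0.005 per mg/l hs-CRP) — on mortality. Diet
and outcome are therefore confounded by construction, which is the premise
the stratified analysis exists to address. Event times come from a Weibull
baseline hazard (default shape 1, scale 125 months — exponential, chosen
for closed-form inverse-CDF sampling and easy oracles) scaled by
`exp(log_hazard())`; independent exponential censoring at rate
0.008/month plus the horizon yields roughly 45% observed mortality over
the full horizon, in line with a long dialysis registry. `censor_rate` is
the *monthly rate* of that censoring process (0 disables it), the reading
under which the sampler's closed-form oracle checks are exact.

Ground-truth nutrient effects are declared per nutrient: null, linear
(β per unit), or U-shaped (curvature · (x − center)², curvature > 0). For
each the generator records the analytic protective interval
{x : f(x) < E[f(X)]} (computed by numeric integration over the truncated
intake marginal), the quantity the pipeline is later scored against.

What it does **not** emulate, hence what passing tests do not show:
non-Gaussian and skewed intake distributions (real thiamine/riboflavin
have SD > mean), seasonal or trend components in diet, informative
censoring and informative visit schedules, within-patient lab drift,
interactions between nutrients, and measurement error structure beyond
i.i.d. noise. Recovery results on this generator demonstrate estimator
correctness under its stated conditions, not clinical validity on any real
cohort.

## Validation design and problem sizes

The test suite pins every layer with an independent oracle where one
exists: brute-force partial-likelihood maximisation for the Cox MLE;
closed-form crossings of known curves for the range extractor; the
integrated survival function for the death fraction; hand-computed
averages on a 3-patient toy cohort for preprocessing; the empirical
survival function for uncensored Kaplan–Meier.

The stochastic properties are checked at sizes chosen to keep the default
run in the minutes range while leaving usable statistical resolution:
protective-interval recovery on 50 cohorts of n = 600 with one unit-SD
U-shaped nutrient (center 5, curvature 0.5 per unit², analytic interval
(4, 6)), requiring both endpoints within ±0.5 in at least 80% of seeds;
null calibration of the stage-1 Wald test and stage-2 nonlinearity F-test
on 1000 lightweight replicates each (rejection within 2 binomial SEs of
5%, plus a Kolmogorov–Smirnov uniformity check on the P values); log-rank
size on 600 replicates; 95% CI coverage on 200 replicates; and a 50-
replicate comparison against the single-stage spline-in-Cox alternative
requiring mean Jaccard overlap of at least 0.5 between the two protective
intervals.

```{r example, fig.width = 6, fig.height = 4}
cfg <- cohort_config(
  n_patients = 300, seed = 5,
  effect_specs = list(effect_spec("zn", "quadratic",
                                  center = 8.18, curvature = 0.06)))
cohort <- generate_cohort(cfg)
profiles <- build_profiles(cohort)
fit <- diet_response(profiles, "zn")
summary(fit)
plot(fit)
cohort$truth$protective_intervals[[1]]$interval
```

## Known limitations

* Points A/B/C are reported without confidence intervals; their sampling
  variability is visible only through the plotted band on the curve.
* The stage-2 F-tests treat the scores as data, ignoring that they are
  themselves estimates; under the null this is calibrated (the suite
  verifies it), but P values under strong signal should be read
  qualitatively.
* The protective range is relative to the group's *average* predicted
  risk, not to an external anchor; ranges are not comparable across groups
  with very different baseline risk.
* With 26 nutrients × 4 groups and no multiplicity correction, some
  "significant" rows are expected by chance; the package reports, it does
  not adjudicate.
* Serum electrolytes remain in the confounder set when the matching
  dietary mineral is the exposure (they are distinct measurements), and
  albumin remains a confounder within albumin strata (it still varies
  there); users who prefer otherwise can pass any confounder list.
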