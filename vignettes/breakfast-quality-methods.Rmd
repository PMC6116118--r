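---
title: "Methods: breakfast adequacy scoring and the cardiometabolic association ladder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: breakfast adequacy scoring and the cardiometabolic association ladder}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(breakfastcmr)
```

`breakfastcmr` operationalizes a cross-sectional pediatric analysis: score
three dimensions of breakfast adequacy from two weekday 24-hour dietary
recalls, derive a panel of cardiometabolic outcomes from fasting
biomarkers and anthropometry, and estimate standardized exposure–outcome
associations under a nested covariate-adjustment ladder. This vignette
records the scientific conventions the package adopts, why each was
chosen where the underlying methodology left the choice open, and what the
simulation-based tests do and do not establish.

## From recall lines to breakfast metrics

A recall file is long-format: one row per food consumed, with an explicit
meal label. Breakfast is identified **by the meal label**, not by clock
time; field protocols for child recalls record the meal slot directly, and
no defensible universal time window exists. Nutrients are resolved
linearly from a per-100 g food-composition library
(`mass × value/100`), so all aggregates are additive and invariant to how
a serving is split across recording lines — both properties are
regression-tested.

**Averaging granularity.** With two recall days per child, breakfast
quality could be computed on day-averaged food composition or per day and
then averaged. The package computes the BQI, BEDs, and BEDb **per day and
averages the metric values across the days on which breakfast was
consumed**. This avoids constructing a chimeric "average breakfast" mixing
foods from different days, and it is the only ordering consistent with the
recall-based definition of skipping (which is a per-day presence
question). A consequence is that an averaged BQI can be half-integral.
Total daily energy is always the mean of both days. A child with breakfast
on only one day contributes that day's metrics, with a partial-presence
flag. Children with fewer than two resolvable recall days are excluded
with a logged reason, mirroring standard completeness rules.

**Skipping.** Two definitions are carried side by side: the questionnaire
item (echoed as reported), and a recall-based definition that requires
breakfast absent on **both** recall days. A habitual skipper can consume
breakfast on a recorded day by chance, so single-day absence is weak
evidence; requiring both days keeps the recall-based definition specific
at the cost of sensitivity, which matches its observed lower prevalence
relative to questionnaire-based skipping.

## BQI scoring conventions

Four items need conventions beyond their one-line definitions:

- **Sugar-rich foods (item iv).** Operationalized as a library tag
  (`sugar_rich`: biscuits, pastries, sugared cereals, jams, soft drinks,
  flavoured milks and similar), with breakfast energy from tagged foods
  compared to 5% of **total daily** energy. The tag lives in the food
  library so a study can re-draw the boundary without touching code.
- **MUFA/SFA ≥ 2 (item vi).** With zero SFA the ratio is undefined; the
  criterion is taken as met when SFA = 0 and MUFA > 0 (the limit of the
  ratio), and not met when both are zero (a fat-free breakfast does not
  demonstrate a favourable fat profile).
- **Energy share 20–25% (item vii).** Inclusive at both ends; a breakfast
  supplying exactly one fifth or one quarter of daily energy meets the
  recommendation as printed.
- **Calcium ≥ 200–300 mg (item ix).** The published range is ambiguous
  about the scoring endpoint. The package scores at the **lower bound,
  200 mg** — the permissive reading — and exposes the threshold as an
  argument (`calcium_threshold_mg`) so the stricter variant is one keyword
  away.

An absent breakfast scores 0 with every item false. The score is always
the count of items met; item viii (cereal + fruit + dairy in the same
meal) is implied by items i–iii jointly, an invariant asserted by tests.

**Energy density.** BEDs divides the energy of solid foods by their mass;
BEDb does the same over energy-containing beverages. Non-energy beverages
(water, zero-kcal drinks) are excluded from **both** denominators: they
carry no energy information and would deflate a density arbitrarily. A
density is missing, not zero, when its mass denominator is empty —
a child with no beverage at breakfast has an undefined BEDb, and such
children drop out of BEDb models as complete-case losses. Oil added to
bread counts as solid mass (it is not drinkable), so olive-oil toast
raises BEDs.

## Cardiometabolic derivations

- **HOMA.** insulin (µU/mL) × glucose (mmol/L) / 22.5, with glucose in
  mg/dL divided by 18.016. The conversion constant is the standard molar
  scaling of the original homeostatic model formulation.
- **Metabolic syndrome.** Five factors at the conventional pediatric
  cutoffs — waist at or above the sex/age 90th percentile, SBP ≥ 130 or
  DBP ≥ 85 mmHg, triglycerides ≥ 150 mg/dL, HDL < 40 mg/dL, glucose
  ≥ 100 mg/dL — with syndrome defined as three or more. Each of the five
  flags contributes one count. All boundaries are exactly as printed
  and are exercised at the boundary in tests. Waist percentiles and the
  component means/SDs must come from an external reference table; the
  package ships a clearly labelled **synthetic** toy reference
  (`synthetic_mets_reference()`) for simulation and testing only.
- **MetS z-score.** Sum of sex/age-specific z-scores of triglycerides,
  HDL, glucose, SBP, and DBP. The HDL term is **negated by default** so
  that a larger composite is always a worse risk profile; summing raw HDL
  would let a protective lipid profile mask hypertension. Because source
  conventions differ, the sign is an argument (`hdl_direction`).
- **Center-wise adiposity z-scores.** The two study centers used similar
  but not identical DXA densitometers, so fat mass index and abdominal fat
  are z-scored within center before pooling, removing any systematic
  between-device shift. Degenerate centers (fewer than two values, or zero
  variance) are an error, not a silent NaN.
- **Log policy.** Triglycerides, GGT, insulin, and HOMA are right-skewed
  in children and are natural-log transformed; all other outcomes pass
  through. The base is immaterial for standardized coefficients (a
  property the tests verify); natural log is used for convention. A
  manifest attribute records the transform applied to each column.

## The association ladder

For each exposure–outcome pair, ordinary least squares is fitted on
complete cases with the exposure and outcome **z-standardized on the
analysis sample**, so the reported coefficient is a standardized β — the
expected SD change in outcome per SD of exposure. Standardizing on the
per-model complete-case sample means each cell's β is interpretable for
exactly the children it was estimated on; covariates are left in their
native units (their scaling cannot change the exposure β). Categorical
covariates (sex, center, maternal education, the puberty indicator) enter
as factors.

The tiers are nested: Model 1 adjusts for sex, age, center, maternal
education and daily energy intake; Model 2 adds fat mass index; Model 3
adds total physical activity. Two structural rules:

- the FMI z-score outcome is never adjusted for FMI, so only Model 1 is
  fitted for it (the abdominal-fat outcome retains all three tiers);
- within activity-defined strata, total physical activity is the
  conditioning variable and is not re-entered as a covariate, so
  stratified fits use the Model 2 set.

p-values are two-sided from the coefficient t-statistic with no
multiplicity correction, and every cell reports its complete-case n —
which can only shrink as the covariate set grows, another tested
invariant. Missing data are handled by complete-case deletion throughout;
no imputation is attempted. A factor covariate that is constant within an
analysis sample (for example, one center absent from a small stratum)
carries no information and is dropped from that fit rather than failing
it; genuine rank deficiency among informative covariates is an error.

The sex-interaction check augments Model 1 with an exposure × sex product
term; the puberty sensitivity analysis refits the ladder with a binary
high-puberty indicator (Tanner stage ≥ III) replacing age.

## The synthetic cohort generator

No individual-level data accompany the methodology, so the package's
test bed is a generator (`generate_cohort()`) that emulates the study
conditions: around 200 children aged 8–12 with overweight/obesity,
47% girls, split across two centers, each with two weekday recalls.
Marginal distributions (age, FMI, waist, blood pressure, lipids, glucose,
insulin, GGT, uric acid, MVPA) are calibrated by moment-matching to the
cohort's published descriptive statistics; the skewed biomarkers are
log-normal with meanlog/sdlog solved from the reported mean and SD.
Breakfast baskets are drawn from a packaged ~35-food library under a
profile weighted toward the milk-with-cocoa / biscuit / sugared-cereal
pattern typical of Spanish schoolchildren, with olive-oil toast and fruit
in a minority; about 5% of children skip breakfast on both days. Lunch,
snack, and dinner are a fixed template scaled per child so total daily
energy lands on a target near 1850 kcal.

The design choice that matters most: outcomes are simulated
**conditional on the breakfast metrics the real scoring code computes**,
not on latent intended values. The generator writes recalls, runs
`score_cohort()` on them, z-scores the resulting BQI/BEDs/BEDb, and only
then builds each outcome as

y* = Σ βₑ·xₑ + Σ γ·confounder + ε,

on the standardized scale, with the residual SD chosen so the total
variance is approximately 1 before mapping back to the outcome's native
(or log-normal) scale. Effects targeted at log-HOMA act through fasting
insulin, since HOMA is derived downstream; the small glucose contribution
to the HOMA variance attenuates the realized standardized effect by under
2%, which the recovery tests absorb. Configuration knobs create a
PA-mediation path (exposure → activity → outcome), stratum-specific
effects, and sex-by-exposure interactions, each recorded in a truth file
along with every generating coefficient.

Children whose exposure is undefined (skippers, or no beverage at
breakfast) contribute no exposure signal — their standardized exposure is
set to zero during generation — and they leave the corresponding
regressions as complete-case losses, exactly as in the real analysis.

**What the simulations show, and what they cannot.** The calibration and
recovery suites establish that *given* data with this generative
structure — linear effects, independent confounders, log-normal skew,
missingness only from undefined exposures — the pipeline's estimates are
unbiased, its null p-values uniform, and mediator adjustment attenuates
as theory predicts. They cannot certify behaviour under features the
generator omits: dietary measurement error and day-to-day intake
correlation, informative missingness, nonlinear dose–response, or
residual confounding. Published coefficient values from any particular
cohort are likewise not reproducible without its data, and the package
does not claim them.

## Numerical choices and problem sizes

- Library invariants (sugar ≤ carbohydrate, MUFA + SFA ≤ fat) allow a
  1e-9 slack for decimal rounding in composition tables.
- Center z-scores and normal-equation comparisons are asserted to 1e-9
  and 1e-8 respectively; standardized-β invariances to 1e-10.
- The calibration suites use 500 replications at n = 200: the null
  rejection count is compared to the exact central 95% binomial interval
  at α = 0.05, and recovery of a standardized effect of 0.25 must show
  |mean bias| < 0.02 with ≥ 93% CI coverage. These sizes give the bias
  estimate a Monte-Carlo SE near 0.003, comfortably below the tolerance,
  while keeping the default test run to a few minutes.
- Generator determinism is bit-exact for a fixed seed, including the
  written CSV files.

## Known limitations

- The BQI's sugar-rich and calcium conventions are declared, configurable
  readings of ambiguous published wording, not inferences of the original
  authors' intent.
- The packaged food library and metabolic-syndrome reference are
  synthetic fixtures with plausible values; neither is a nutrition or
  clinical reference.
- The whether-to-negate-HDL convention changes the MetS z-score's scale;
  composites computed under different conventions are not comparable.
- Activity classification consumes already-summarized MVPA minutes;
  raw accelerometry processing (wear-time rules, cut-points) is out of
  scope.
- The recall-based skipping definition is descriptive only; skipping is
  not modelled as a regression exposure.
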