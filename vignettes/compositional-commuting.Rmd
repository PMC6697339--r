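---
title: "Compositional analysis of commuting and discretionary-time behaviour: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Compositional analysis of commuting and discretionary-time behaviour: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codamove)
```

## The scientific problem

Time spent in movement behaviours is co-dependent: within a fixed budget,
more of one activity necessarily means less of others. Treating minutes of
screen time, recreational walking and sport/DIY as independent outcomes
therefore misstates both the estimand and the error structure. `codamove`
analyses the *discretionary-time subcomposition* — screen time, walking
for pleasure, and sport/DIY activities, in minutes/week — as compositional
data: only the relative information (ratios of parts) is modelled, and the
absolute scale is carried separately as total discretionary time. The
scientific exposure of interest is active commuting (walking, cycling or
public transport versus car-only travel to work), cross-sectionally and as
a four-level change variable across two assessments.

## Variable derivation

Raw questionnaire responses are converted deterministically:

* Screen time: daily TV and computer hours are summed, truncated at 9
  hours/day (applied to the *sum*, matching the stated order of
  operations), and converted to minutes/week.
* Activities: each of five activities (walking for pleasure, strenuous
  sport, other sport, light DIY, heavy DIY) is reported as frequency and
  duration categories. Weekly minutes = occasions/week x midpoint minutes
  of the duration category (22.5 for "15-30 minutes"). Monthly frequencies
  are divided by the mean number of weeks per month, 365.25/7/12 ~= 4.348 —
  the conversion is configurable because only the coding principle, not
  the divisor, is standard. The full category lists are configurable
  (`default_category_maps()`); only one anchor example per scale is fixed
  by convention, so the shipped lists are a documented default, not a
  claim about any particular instrument.
* The subcomposition: walking stands alone; the four sport/DIY items are
  amalgamated into one part because they are individually zero-heavy.

Exclusions are applied in a fixed order, one reason recorded per dropped
record: not employed / no commute mode; commuting less than once a week or
zero miles (assumed home-working); unable to walk; zero screen time; more
than 24 h/day of discretionary time; and finally complete-case filtering
on exposure, outcomes and covariates. The complete-case step is last so
that the ledger mirrors a sample-flow diagram. Where both assessments of a
longitudinal pair are present, the filters are applied per assessment and
the pair is retained only if both rows survive — the per-assessment choice
is deliberate: the home-working and walking-ability conditions describe a
state at the time of reporting, not a fixed trait.

## Compositional machinery

All log-ratios use natural logarithms. A sequential binary partition over
the three parts defines an orthonormal isometric log-ratio (ilr) basis;
with the default partition the first balance is

$$z_1 = \sqrt{2/3}\,\ln\!\frac{\text{screen}}{\sqrt{\text{walking}\cdot\text{sport/DIY}}},\qquad
z_2 = \sqrt{1/2}\,\ln\!\frac{\text{walking}}{\text{sport/DIY}}.$$

The isolated part is always the numerator, so positive regression
coefficients mean relatively *more* of that part. The three pivot bases
(`pivot_bases()`) each isolate one part in their first balance; the three
coordinate sets are orthogonal rotations of each other, which is why
multivariate tests agree across them to numerical precision (asserted at
1e-8) while their first coordinates isolate different parts. Algebraic
identities (round trip through `ilr_inverse()`, scale invariance,
subcompositional coherence of the walking:sport balance) are tested at
1e-10; identities passing through `exp()` use 1e-8.

### Rounded zeros

Zeros in walking and sport/DIY are treated as *rounded*: the categorical
response scales cannot express values below their smallest product
(lowest frequency x lowest duration midpoint), so "none" is interpreted
as below-detection-limit rather than as structural absence. Screen time
must be positive (records violating this are excluded), giving the
imputation a complete reference part. The default algorithm
(`replace_zeros(method = "lrEM")`) expresses each row in additive
log-ratios with respect to screen time, treats zeros as left-censored at
`log(dl/screen)`, and iterates regression-based conditional-expectation
imputation under the censoring bound — an EM scheme for censored
log-ratio data. A multiplicative replacement (0.65 x detection limit with
closure-preserving shrinkage of the other parts) is available as a
flagged alternative. Both guarantee imputed values strictly below the
detection limit. The published analyses this package generalises used a
log-ratio data-augmentation imputation whose settings are not public; the
EM default is this package's own documented choice, validated by
censoring-and-recovery simulation (geometric means restored within 25% at
a 20% zero rate), not a re-implementation of any specific prior software.

Default detection limits: the smallest observable category product for
walking, and twice that for sport/DIY (an amalgam of four scales can
first register activity at the same product, but its typical smallest
reports combine two items; the factor is configurable and results are
insensitive to it at these zero rates).

## Regression stages

* **Coordinate-set models** (`fit_coordinate_set()`): a two-response
  linear model tested by MANCOVA-style statistics. Both Pillai's trace
  (primary) and Wilks' lambda are reported, because the source analyses
  name only "MANCOVA" without fixing the statistic; with two responses
  and these sample sizes the two agree closely.
* **Balance models** (`fit_balance_model()`): OLS on the first coordinate
  of each pivot set, giving one coefficient per part-vs-rest contrast.
* **Total models** (`fit_total_model()`): OLS on log total minutes/week.
* **Longitudinal models** (`fit_longitudinal()`): follow-up outcome
  adjusted for its baseline value plus the four-level commute-change
  factor (reference: stable inactive).

Adjustment tiers: tier 1 exposure only; tier 2 adds travel frequency and
distance plus eleven socio-demographic covariates; tier 3 adds five
health/occupation covariates and, longitudinally, elapsed years and a
season-change indicator. Categorical covariates use treatment contrasts
with the most frequent level as reference (recorded in each fit); income
and education enter as unordered factors; age, Townsend score, BMI,
distance and frequency as continuous. No multiple-testing adjustment is
applied, matching per-model reporting. The sensitivity variant drops
income and household children from tiers >= 2, enlarging the
complete-case sample when those covariates carry missingness.

## Adjusted means and back-transformation

`build_reference_grid()` re-implements proportional-weighting adjusted
means for linear models: continuous covariates at their sample mean,
factor dummy columns at their observed frequencies, exposure varied. For
a linear model this is identical to averaging per-row predictions with
the exposure overridden (asserted at 1e-10, and cross-checked against
`emmeans` with `weights = "proportional"`); observed-frequency weighting
was chosen over equal weighting because the estimand is the adjusted mean
in the analysed population. Group ilr means are inverse-transformed to
proportions and rescaled by the group's adjusted total, so per-part
minutes sum exactly to the group total by construction. The adjusted
total is `exp(mean log total)` — a geometric-mean-scale quantity, kept
deliberately bias-uncorrected so that an intercept-only pipeline
reproduces the compositional mean exactly; a Duan smearing factor is
available behind a flag for readers who want an arithmetic-scale total.
Whether the published adjusted totals were arithmetic or geometric is not
stated; the geometric default is the internally consistent choice here,
and the two differ by the factor `E[exp(resid)]` (~13% at a residual SD
of 0.5), which matters only for absolute minutes, not for contrasts.

## The synthetic cohort generator

Real cohort data of this kind are access-controlled, so validation runs
on synthetic cohorts with known generating parameters
(`cohort_config()`, `generate_cross_sectional()`,
`generate_longitudinal()`).

The generator draws the *latent* composition on the ilr scale — bivariate
normal coordinates given exposure and covariates, plus an independent
log-normal total — and only then coarsens it into questionnaire
responses. Generating on the ilr scale makes the downstream linear models
correctly specified, so parameter recovery is a fair test of the
machinery rather than of model misspecification. Defaults reproduce the
documented study conditions: baseline geometric-mean composition
(1270, 18, 51) min/week with arithmetic mean total 1724 (the log-total
mean carries the -sigma^2/2 correction so the *arithmetic* mean is
calibrated); 35% active commuters; commute-change transition rates of
0.111 (inactive to active) and 0.243 (active to inactive); elapsed time
~ Normal(4.3, 0.9) years truncated positive; covariate marginals of a
middle-aged, predominantly White, employed cohort. Residual spread —
balance SDs of about 1.3 and 1.1 with correlation ~0.27, log-total SD
0.5 — was back-derived from the confidence-interval widths such cohorts
report for commute-mode contrasts at known group sizes; these are realism
choices fixed in the defaults, not fitted quantities.

Coarsening mirrors the instrument: screen time is reported as whole daily
TV and computer hours (a random TV share in 0.4-0.8, each rounded);
walking and sport/DIY are mapped to the nearest frequency x duration
category product on the log scale (deterministic tie-break); sport/DIY
minutes are split across one or two of the four constituent activities.
Zeros arise from the coarsening itself: participants below a reporting
threshold answer "none". The threshold is the latent quantile at the
configured zero rate (defaults 0.30 walking, 0.10 sport/DIY, consistent
with a walking lower quartile of zero), which entangles zeros with low
latent values exactly as the rounded-zero model assumes.

What the generator does *not* emulate: genuine confounding structure
unless switched on (`confounding`), nonlinear covariate effects,
informative missingness, digit preference and recall bias in self-report,
and geographic clustering. Passing recovery tests therefore demonstrate
that the *pipeline* is consistent and approximately unbiased under its
own assumptions — not that those assumptions hold in any real cohort.
The categorical coarsening plus imputation does inject a small,
realistic attenuation/leakage (of order 0.01-0.04 on balance effects of
0.15) which the coverage tests absorb within their 0.90-0.98 acceptance
band; this is a deliberate feature of testing end-to-end rather than on
latent data.

## Problem sizes and numerical choices

Validation uses cohorts of n = 2,000 over 200 replicates for coverage,
n = 400 over 1,000 replicates for the null rejection rate, and n = 50,000
once for generator calibration — sizes at which Monte-Carlo error is
small relative to the acceptance bands while the whole suite stays fast.
EM imputation converges at 1e-8 on the censored cells (cap 100
iterations); the truncated-normal mean uses a log-scale Mills ratio for
stability far below the censoring bound. Degenerate inputs fail loudly:
constant exposures, rank-deficient designs (aliased columns are named),
non-positive parts or totals, zero screen time at the imputation stage,
and mismatched coordinate/basis tags are all errors, not warnings.

## Known limitations

Only three-part compositions are exercised end to end (the SBP/ilr code
is general, but zero replacement assumes a single complete part);
standard errors for back-transformed minutes are intentionally not
provided (the nonlinear transform would need delta-method or bootstrap
machinery); and the longitudinal model is a follow-up-adjusted-for-
baseline OLS, not a mixed model — appropriate for exactly two assessments
but not more.
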