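---
title: "Dietary inflammatory scoring and liver-disease survival models: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dietary inflammatory scoring and liver-disease survival models: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(diisurv)
```

## Scope

`diisurv` implements an epidemiological pipeline linking the inflammatory
potential of diet to chronic liver disease (CLD) incidence and progression:
per-participant dietary scores (DII, energy-adjusted eDII, HEI-2020, MEDS),
cohort construction with a one-year landmark, and survival inference (Cox
proportional hazards with quartile trend tests, restricted-cubic-spline
nonlinearity tests, Schoenfeld diagnostics with an AFT fallback, Fine-Gray
competing-risk models, progression and subgroup analyses). Because the
motivating cohort data are access-restricted, the package ships a synthetic
cohort generator that reproduces the *statistical structure* the analysis
assumes, so every stage is exercised end-to-end without any download.

## The Dietary Inflammatory Index

For participant $i$ and dietary parameter $j$ with global reference mean
$\mu_j$, SD $\sigma_j > 0$ and inflammatory weight $w_j$:

$$z_{ij} = \frac{x_{ij} - \mu_j}{\sigma_j}, \qquad
  p_{ij} = 2\,\Phi(z_{ij}) - 1, \qquad
  \mathrm{DII}_i = \sum_j w_j\, p_{ij}.$$

The centred percentile $p_{ij}$ lies strictly inside $(-1, 1)$, so
$|\mathrm{DII}_i| \le \sum_j |w_j|$ always, and a diet sitting exactly at
every reference mean scores 0. The source description of this step says
only that Z-scores are "converted to percentiles, ranging from −1 to 1";
we adopt the doubled-normal-CDF convention standard in the DII literature,
and expose an empirical alternative (`mode = "empirical"`, a centred
within-cohort rank transform) for users who prefer a distribution-free
percentile. The two agree in ranking but not numerically; all shipped
defaults use the normal transform.

The eDII applies the identical machinery to nutrient *densities*
(intake per 1,000 kcal of total energy) scored against a density reference
table. When no external density reference is available the package derives
density means/SDs from the scored cohort itself — adequate for internal
ranking, but the resulting scores are then relative to the cohort rather
than to a global population, and this is deliberately a documented fallback
rather than the default contract.

The shipped 29-parameter reference table (`dii_reference()`) uses
literature-derived placeholder means, SDs and weights in the style of the
original DII global database. It is explicitly user-replaceable
(`read_dii_reference()`), because any serious application should drop in
the reference table actually matched to its instrument. Records missing any
reference parameter are a hard error, never silently renormalised: partial
scores are not comparable across participants.

## Diet-quality indices

*HEI-2020* scores 13 components against adequacy and moderation standards
on the density scale (amounts per 1,000 kcal; a fatty-acid ratio and two
percent-of-energy components). Within each component the score is linear
between the two standards and clamped at the points ceiling; moderation
components are scored in reverse. Totals are in [0, 100] and invariant to
proportional scaling of all intakes and energy. The standards table is
shipped as data (`hei_standards()`) and is replaceable.

*MEDS* awards one point per beneficial component at or above the cohort
median, one per detrimental component below the median, and one for
alcohol inside a moderate range, totalling 0–9. The original instrument is
ambiguous on two points we had to decide: medians default to the overall
cohort (a `sex` argument switches to sex-specific cutoffs), and the
moderate alcohol range defaults to 5–25 g/day for both sexes — an
assumption, exposed in `meds_config()`.

## Cohort construction

Exclusions are applied in a fixed order, one logged reason per dropped
participant: missing required fields first, then a prior liver-disease or
malignancy flag, then the one-year landmark (any event *or censoring*
before 365.25 days; exactly 365.25 days is retained). The landmark guards
against reverse causation from subclinical disease at baseline.

Covariate reclassification follows the motivating cohort's conventions:
education codes collapse to High (degree) / Median (A-levels, HND/HNC,
professional) / Low (O-levels, CSE, none, prefer-not-to-answer); the
questionnaire's published coding lists "prefer not to answer" under a code
that collides with O-levels, so the package keeps the sentinel value −3
for it. Blood pressure maps to normal / elevated / stage 1 / stage 2 with
the standard systolic-or-diastolic "or" logic; gap cases such as SP
120–129 with DP 80–89 are stage 1 via the diastolic criterion. Age and
deprivation are median-split at 58 years and −2.3 (age at the cutoff goes
to "older", deprivation at the cutoff to "low"); both cutoffs and boundary
sides are arguments, since only the cutoffs themselves are prescribed.

Exposure quartiles are rank-based with the remainder given to the first
groups — with $n = 4q + r$ distinct scores the first $r$ quartiles get the
extra member, which reproduces the published group sizes
30,333 / 30,332 / 30,332 / 30,332 at $n = 121{,}329$. Ties share the
quartile of the first rank in their tie block; a fully tied score vector
degenerates to Q1 with a warning rather than an error.

## Survival models

All fits use the `survival` package underneath the module interfaces; the
package's own contribution is the scoring, cohort construction, spline
basis, test assembly and the generator, not a re-derivation of standard
estimators.

- **Cox models** maximise the partial likelihood with Efron tie handling
  (Breslow behind a flag). Adjustment tiers: 1 = unadjusted, 2 = age, sex,
  ethnicity, education, deprivation; 3 adds alcohol, smoking, BMI,
  physical activity, blood-pressure category and diabetes. The source
  analysis never enumerates its first two models; this tiering is our
  definition and is configurable. Events other than the modelled outcome
  are censored (cause-specific hazards).
- **Trend test**: each quartile label is replaced by its within-cohort
  median exposure and the model refit; the Wald p-value of that continuous
  term is the "P for trend". A Wald statistic (not score/LR) is the
  default throughout; the choice is invisible at these event counts.
- **Restricted cubic splines** use the truncated-power natural basis,
  normalised by the squared knot range, with 4 knots at the
  5th/35th/65th/95th exposure percentiles (3–5 knots supported, at the
  conventional quantile sets). The basis is exactly linear at and below
  the first knot. `overall_p` is a Wald test of all spline terms,
  `nonlinear_p` of the non-linear terms only.
- **Schoenfeld diagnostics** use scaled residuals against the
  Kaplan–Meier time transform; when the global test fails at 0.05 the
  analysis plan falls back to a **Weibull AFT** model (log-normal and
  log-logistic optional), reported as time ratios. Fixing the Weibull
  scale at 1 recovers the exponential AFT exactly.
- **Fine-Gray models** follow the 1999 subdistribution formulation:
  subjects with competing events remain in later risk sets with
  inverse-probability-of-censoring weights $G(t)/G(\min(T_i, t))$ from a
  covariate-free Kaplan–Meier fit of the censoring distribution
  (`survival::finegray` performs the expansion), with a robust sandwich
  variance clustered on subject. With no competing events the model
  reduces to the Cox fit exactly — within optimiser tolerance — and the
  test suite verifies the estimate against a hand-written grid-search
  maximisation of the IPCW-weighted partial likelihood on a six-subject
  worked example.
- **Progression analysis** restricts to incident cases and resets the
  time origin to diagnosis; for exponential progression hazards the
  origin shift leaves the HR invariant, which the suite checks.
- **Subgroup analyses** refit the adjusted model per stratum (dropping
  the stratifier, and its continuous parent for derived splits such as
  the age group); heterogeneity is a Wald test of exposure-by-stratifier
  product terms in a pooled shared-baseline model. An option stratifies
  the baseline too, making the saturated-interaction model exactly
  equivalent to the separate stratum fits. Interactions use the
  continuous exposure, matching the per-unit framing of the estimates.

## The synthetic cohort generator

`sim_config()` defaults *are* the study conditions, chosen once:

- **Nutrient intakes** are multivariate log-normal with exchangeable
  correlation 0.2, moment-matched so each parameter's arithmetic mean and
  SD equal the reference table's. A standard-normal latent diet factor,
  loaded with sign $\mathrm{sign}(w_j)$ and strength 0.25, couples diet to
  current smoking, BMI, age and sex, so that high-score quartiles are
  younger, heavier and smoke more — the qualitative gradients a real
  cohort table shows.
- **Events** are cause-specific exponentials in weeks. The CLD log-hazard
  is `0.0325` per DII unit (the published continuous effect size) plus
  modest covariate effects; competing cirrhosis, liver cancer and death
  run at configured flat rates (4e-6, 2.5e-6, 5.5e-5 per week) chosen to
  reproduce the published order of magnitude of case counts;
  the baseline CLD rate 4e-5/week yields roughly a 3% cumulative
  incidence over the follow-up window. Administrative censoring is
  `650 − U(0, 90)` weeks, emulating staggered recruitment with a median
  follow-up near 604 weeks.
- **Biomarkers** are affine in the standardised DII with noise scaled
  analytically so the *population* correlation equals the target
  (defaults 0.062, 0.054, 0.053 for WBC, neutrophils, CRP); they are kept
  Gaussian for exactness of that calibration, so the CRP margin is not
  skewed as real CRP would be.
- **Progression** draws post-diagnosis exponential times with log-HR
  0.104 per DII unit for cirrhosis (the published effect) and 0 for liver
  cancer (where the source found no association).

What the generator does *not* emulate: diagnostic coding noise, joint
covariate dependence beyond the single latent factor, non-exponential
baselines (a Weibull option exists only in the AFT tests' own simulators),
and real food-to-nutrient mappings. Passing tests therefore demonstrate
correctness of the pipeline's arithmetic and estimator calibration under
the stated model, not fidelity to any particular real cohort.

## Numerical and testing choices

Determinism: a configuration's seed fully determines the generated tables;
the progression generator offsets the seed by one so that cohort and
progression draws do not share a stream. Degenerate inputs fail loudly
(non-positive SDs and energies, missing parameters, constant covariates,
zero-event strata) rather than returning silently renormalised results.

Test problem sizes are desk-scale choices: tiny fixtures for the
brute-force likelihood oracles (grid search over $[-8, 8]$ refined to
$5 \times 10^{-6}$ resolution), 100 cohorts of $n = 20{,}000$ for
parameter recovery and confidence-interval coverage, 200 replicates at
$n = 10{,}000$ (splines) and $n = 5{,}000$ (Schoenfeld) for size and
power, $n = 100{,}000$ for the biomarker-correlation calibration, and a
single $n = 100{,}000$ cohort in the acceptance script — the same order
as the published analysis. Monotone-likelihood draws (all events in one
covariate arm of a tiny dataset) have no finite maximiser and are skipped
by the randomized oracle comparison.

## Known limitations

The shipped DII reference is a placeholder, not the instrument-matched
table; eDII's cohort-derived fallback changes the score's interpretation;
HEI-2020 food groups must be supplied, not derived from nutrients; the
Fine-Gray censoring model ignores covariates (the standard formulation);
and the generator's single-factor diet–covariate coupling cannot produce
confounding structures richer than it encodes.
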