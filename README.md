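# diisurv

Dietary inflammatory scoring and survival analysis of chronic liver
disease (CLD) risk.

Pro-inflammatory diets are a suspected driver of liver disease. The
standard instrument for quantifying a diet's inflammatory potential is
the Dietary Inflammatory Index (DII): for each of 29 dietary parameters
the intake is standardised against a global reference
(*z* = (*x* − *μ*)/*σ*), mapped to a centred percentile
*p* = 2Φ(*z*) − 1 ∈ (−1, 1), multiplied by the parameter's inflammatory
weight *w*, and summed,

> DII = Σ<sub>j</sub> w<sub>j</sub> · (2Φ(z<sub>j</sub>) − 1).

Higher scores mean a more pro-inflammatory diet. `diisurv` implements
this score (plus the energy-adjusted eDII on densities per 1,000 kcal,
the 13-component HEI-2020 and the 9-point Mediterranean Diet Score), the
construction of an analysis-ready cohort (exclusion rules, one-year
landmark, covariate reclassification, exposure quartiles), and the
inference layer an epidemiologist needs for this question:

- Cox proportional hazards models (Efron ties) for quartile and
  continuous exposures, with tiered covariate adjustment and the
  quartile-median "P for trend";
- restricted cubic spline tests of dose–response nonlinearity;
- Schoenfeld proportional-hazards diagnostics with a Weibull AFT
  fallback;
- Fine-Gray subdistribution hazard models with cirrhosis, liver cancer
  and death as competing events (IPCW weighting, robust variance);
- progression analysis among incident cases, subgroup/interaction
  analyses, and DII–biomarker correlations.

Because the motivating cohort is access-restricted, a seeded synthetic
cohort generator (`sim_config()`, `generate_cohort()`) reproduces the
statistical structure the analysis assumes — correlated log-normal
intakes, realistic covariate marginals, cause-specific hazards with a
configurable DII effect, competing events, staggered administrative
censoring, calibrated biomarkers — so the whole pipeline runs and is
tested end-to-end on any machine. It is intended for methodologists,
teaching, and as scaffolding for groups holding the real data.

## Worked example

```r
library(diisurv)

cfg  <- sim_config(n = 20000, seed = 1)   # defaults = study conditions
raw  <- generate_cohort(cfg)
built <- build_cohort(raw$intakes, raw$covariates, raw$followup,
                      reference = cfg$reference)
coh  <- built$cohort                       # 19,190 retained; 810 excluded

fit_cox(coh, "dii", "quartile", tier = 3, ph_test = FALSE)
#> Cox PH model (tier 3): dii [quartile] -> cld; 565 events / 19190 subjects
#>   term    hr ci_low ci_high       p
#> 1   Q2 1.061 0.8331   1.352 0.63033
#> 2   Q3 1.232 0.9741   1.557 0.08177
#> 3   Q4 1.085 0.8498   1.385 0.51307
#> P for trend: 0.3198

fit_fine_gray(coh, "dii", "continuous", tier = 3)
#> Fine-Gray model (tier 3): dii [continuous] -> cld (competing: cirrhosis,
#>   liver_cancer, death); 565 events
#>   term   shr ci_low ci_high      p
#> 1  dii 1.018 0.9688    1.07 0.4799

rcs_nonlinearity(coh, "dii", tier = 3)
#> Restricted cubic spline Cox fit for 'dii' (4 knots)
#>   knots: -2.6554, -0.3976,  0.9808,  2.8607
#>   overall p = 0.8005; nonlinear p = 0.7695
```

Reading the output: hazard ratios are per quartile (Q1 reference) or per
DII unit; the subdistribution HR (sHR) accounts for competing events; the
non-linear p tests departure from a linear dose–response. At n = 20,000
(~565 events) a true per-unit log-HR of 0.0325 is within the confidence
interval but not individually significant — the published effect sizes
need cohort-scale event counts, which is why the test suite checks
calibration across 100 replicate cohorts rather than significance in one.

`run_pipeline(out_dir)` executes the whole chain (score → build → fit →
subgroups → sensitivity) and writes diffable CSV outputs plus a manifest
with the seed and configuration hash. A thin command-line wrapper for the
main verbs is installed at `inst/cli/dii-pipeline.R`.

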