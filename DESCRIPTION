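Package: diisurv
Title: Dietary Inflammatory Scoring and Chronic Liver Disease Survival Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the Dietary Inflammatory Index (DII) and its
    energy-adjusted variant (eDII) from per-participant nutrient intakes,
    together with the Healthy Eating Index 2020 and a median-cutoff
    Mediterranean Diet Score; builds analysis-ready epidemiological cohorts
    (inclusion/exclusion rules, one-year landmark, covariate
    reclassification, exposure quartiles); and estimates diet to
    liver-disease associations with Cox proportional hazards models,
    quartile-median trend tests, restricted cubic spline nonlinearity
    tests, Schoenfeld diagnostics with Weibull accelerated failure time
    fallback, Fine-Gray subdistribution hazard models for competing risks,
    progression analyses among incident cases, subgroup and interaction
    analyses, and biomarker correlations. A configurable synthetic-cohort
    generator emulates the assumed data structure so the whole pipeline is
    testable without access-restricted data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    survival,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
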