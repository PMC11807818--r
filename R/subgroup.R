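#' Stratified (subgroup) analysis with an interaction test
#'
#' Fits the tier-adjusted Cox model within each level of a categorical
#' stratifier (the stratifier itself is dropped from the covariate set),
#' and tests effect heterogeneity with a Wald test of the exposure-by-
#' stratifier product terms in the pooled model. The continuous exposure
#' is used for the interaction, matching the per-unit framing of the
#' stratum estimates.
#'
#' @inheritParams fit_cox
#' @param stratifier Name of a categorical cohort column.
#' @param stratified_baseline If `TRUE`, the pooled interaction model also
#'   stratifies the baseline hazard by the stratifier (with every
#'   covariate interacted this makes the pooled model exactly equivalent
#'   to the separate stratum fits); default `FALSE`, the usual shared-
#'   baseline interaction test.
#' @return An object of class `dii_subgroup`: per-stratum data.frame
#'   (`stratum`, `hr`, `ci_low`, `ci_high`, `p`, `n`, `n_events`) and
#'   `interaction_p`. Strata without events are flagged and skipped with a
#'   warning.
#' @export
subgroup_analysis <- function(cohort, stratifier, exposure = "dii",
                              tier = 3, outcome = "cld", conf_level = 0.95,
                              stratified_baseline = FALSE) {
  if (!stratifier %in% names(cohort))
    stop("invalid input: cohort lacks stratifier column '", stratifier, "'")
  strat <- factor(cohort[[stratifier]])
  if (nlevels(strat) < 2L)
    stop("invalid input: stratifier '", stratifier, "' has fewer than 2 levels")
  covs <- setdiff(tier_covariates(tier), stratifier)
  # bp_category is derived from systolic/diastolic; age_group/tdi_group from
  # age/tdi -- when stratifying on a derived split, drop its continuous parent
  parent <- c(age_group = "age", tdi_group = "tdi")
  if (stratifier %in% names(parent)) covs <- setdiff(covs, parent[[stratifier]])

  rows <- list()
  for (lev in levels(strat)) {
    sub <- cohort[strat == lev, , drop = FALSE]
    nev <- sum(sub$event == outcome)
    if (nev == 0L) {
      warning("stratum '", lev, "' has no '", outcome, "' events; skipped")
      rows[[lev]] <- data.frame(stratum = lev, hr = NA, ci_low = NA,
                                ci_high = NA, p = NA, n = nrow(sub),
                                n_events = 0L, stringsAsFactors = FALSE)
      next
    }
    f <- fit_cox_raw(sub, exposure, covs, outcome, conf_level)
    rows[[lev]] <- data.frame(stratum = lev, f$tab, n = nrow(sub),
                              n_events = nev, stringsAsFactors = FALSE)
  }
  strata_tab <- do.call(rbind, rows)
  rownames(strata_tab) <- NULL

  # pooled model with exposure x stratifier product terms
  d <- data.frame(.time = cohort$follow_up_weeks,
                  .status = as.integer(cohort$event == outcome),
                  .expo = cohort[[exposure]], .strat = strat)
  d[covs] <- cohort[covs]
  check_model_columns(d, covs)
  form <- stats::as.formula(paste(
    "survival::Surv(.time, .status) ~ .expo * .strat",
    if (length(covs)) paste("+", paste(covs, collapse = " + ")) else "",
    if (stratified_baseline) "+ survival::strata(.strat)" else ""))
  pooled <- survival::coxph(form, data = d, ties = "efron")
  co <- stats::coef(pooled)
  idx <- grep("^\\.expo:", names(co))
  idx <- idx[!is.na(co[idx])]
  inter <- wald_test(co, stats::vcov(pooled), idx)

  structure(list(stratifier = stratifier, exposure = exposure,
                 tier = as.integer(tier), outcome = outcome,
                 strata = strata_tab, interaction_p = inter$p,
                 pooled_fit = pooled), class = "dii_subgroup")
}

## Minimal Cox fit with an explicit covariate list (used within strata,
## where the tier set minus the stratifier is needed).
fit_cox_raw <- function(cohort, exposure, covs, outcome, conf_level = 0.95) {
  d <- data.frame(.time = cohort$follow_up_weeks,
                  .status = as.integer(cohort$event == outcome),
                  .expo = cohort[[exposure]])
  d[covs] <- lapply(cohort[covs], function(v) if (is.factor(v)) droplevels(v) else v)
  keep <- vapply(covs, function(cl) length(unique(d[[cl]])) > 1L, logical(1))
  covs <- covs[keep]
  fit <- survival::coxph(model_formula(covs), data = d, ties = "efron")
  co <- stats::coef(fit)[".expo"]
  se <- sqrt(diag(stats::vcov(fit)))[".expo"]
  tab <- hr_table(co, se, conf_level)
  tab$term <- NULL
  list(tab = tab, fit = fit)
}

#' @export
print.dii_subgroup <- function(x, ...) {
  cat(sprintf("Subgroup analysis of %s -> %s by '%s' (tier %d)\n",
              x$exposure, x$outcome, x$stratifier, x$tier))
  print(format(x$strata, digits = 4))
  cat(sprintf("P for interaction: %.4g\n", x$interaction_p))
  invisible(x)
}

#' Restrict the cohort to participants with a typical dietary pattern
#'
#' Sensitivity subset: keeps only participants whose diet at assessment
#' was flagged as typical of their usual intake, reducing exposure
#' misclassification from transient dietary change. Downstream fits use
#' the returned subset unchanged.
#'
#' @param cohort Cohort data.frame.
#' @param flag Name of the logical flag column (default `"typical_diet"`).
#' @return The flagged subset of `cohort`.
#' @export
typical_diet_subset <- function(cohort, flag = "typical_diet") {
  if (!flag %in% names(cohort))
    stop("invalid input: cohort lacks flag column '", flag, "'")
  cohort[cohort[[flag]] %in% TRUE, , drop = FALSE]
}

#' Correlation between the DII and inflammatory biomarkers
#'
#' Per-biomarker correlation (Pearson by default, Spearman optional)
#' between the dietary inflammatory score and circulating inflammation
#' markers such as white blood cell count, neutrophils and C-reactive
#' protein, on pairwise-complete observations.
#'
#' @param dii Numeric score vector.
#' @param biomarkers Data.frame of numeric biomarker columns, same length.
#' @param method `"pearson"` (default) or `"spearman"`.
#' @return Data.frame with `biomarker`, `r`, `p`, `n`, `method`.
#' @export
biomarker_correlation <- function(dii, biomarkers,
                                  method = c("pearson", "spearman")) {
  method <- match.arg(method)
  if (!is.data.frame(biomarkers))
    biomarkers <- as.data.frame(biomarkers)
  if (nrow(biomarkers) != length(dii))
    stop("invalid input: dii and biomarkers must have the same length")
  rows <- lapply(names(biomarkers), function(nm) {
    y <- biomarkers[[nm]]
    ok <- is.finite(dii) & is.finite(y)
    if (sum(ok) < 3L)
      stop("insufficient data: fewer than 3 complete pairs for '", nm, "'")
    ct <- stats::cor.test(dii[ok], y[ok], method = method, exact = FALSE)
    data.frame(biomarker = nm, r = unname(ct$estimate), p = ct$p.value,
               n = sum(ok), method = method, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
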