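## Adjustment tiers. Model 1 is unadjusted; model 2 adds the
## sociodemographic block; model 3 is the full covariate set used for the
## primary analyses (age, sex, ethnicity, education, deprivation, alcohol,
## smoking, BMI, physical activity, blood pressure, diabetes).
tier_covariates <- function(tier) {
  tier <- as.integer(tier)
  if (!tier %in% 1:3) stop("invalid input: tier must be 1, 2 or 3")
  t2 <- c("age", "sex", "ethnicity", "education", "tdi")
  switch(tier, character(0), t2,
         c(t2, "alcohol", "smoking", "bmi", "physical_activity",
           "bp_category", "diabetes"))
}

check_model_columns <- function(cohort, cols) {
  miss <- setdiff(cols, names(cohort))
  if (length(miss))
    stop("invalid input: cohort lacks column(s): ", paste(miss, collapse = ", "))
  for (col in cols) {
    v <- cohort[[col]]
    if (length(unique(v[!is.na(v)])) < 2L)
      stop("non-identifiable: covariate '", col, "' is constant")
  }
  invisible(TRUE)
}

## Wald chi-square test of a coefficient subset against zero.
wald_test <- function(coefs, vcov, idx) {
  b <- coefs[idx]
  V <- vcov[idx, idx, drop = FALSE]
  stat <- drop(t(b) %*% solve(V) %*% b)
  list(chisq = stat, df = length(idx),
       p = stats::pchisq(stat, df = length(idx), lower.tail = FALSE))
}

## HR / CI / p rows for a set of coefficients from a coxph-like fit.
hr_table <- function(coefs, se, conf_level = 0.95) {
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  data.frame(term = names(coefs),
             hr = exp(coefs),
             ci_low = exp(coefs - zq * se),
             ci_high = exp(coefs + zq * se),
             p = 2 * stats::pnorm(-abs(coefs / se)),
             row.names = NULL, stringsAsFactors = FALSE)
}

build_model_frame <- function(cohort, exposure, exposure_type, tier, outcome,
                              time_col = "follow_up_weeks",
                              event_col = "event") {
  covs <- tier_covariates(tier)
  if (exposure_type == "quartile") {
    qcol <- paste0(exposure, "_quartile")
    if (!qcol %in% names(cohort)) {
      if (!exposure %in% names(cohort))
        stop("invalid input: cohort lacks exposure column '", exposure, "'")
      cohort[[qcol]] <- assign_quartiles(cohort[[exposure]])
    }
    expo <- cohort[[qcol]]
  } else {
    if (!exposure %in% names(cohort))
      stop("invalid input: cohort lacks exposure column '", exposure, "'")
    expo <- cohort[[exposure]]
  }
  check_model_columns(cohort, covs)
  d <- data.frame(.time = cohort[[time_col]],
                  .status = as.integer(cohort[[event_col]] == outcome),
                  .expo = expo, stringsAsFactors = FALSE)
  d[covs] <- cohort[covs]
  list(data = d, covs = covs)
}

model_formula <- function(covs, response = "survival::Surv(.time, .status)") {
  stats::as.formula(paste(response, "~",
                          paste(c(".expo", covs), collapse = " + ")))
}

#' Fit a Cox proportional hazards model for a diet-score exposure
#'
#' Maximises the Cox partial likelihood (Efron tie handling by default)
#' for a scored exposure, either as quartiles (Q1 reference) or as a
#' continuous per-unit term, with tiered covariate adjustment: tier 1
#' unadjusted, tier 2 age/sex/ethnicity/education/deprivation, tier 3 the
#' full covariate set. Events other than `outcome` are treated as censored
#' (cause-specific hazard).
#'
#' @param cohort Analysis-ready cohort from [build_cohort()] (or any
#'   data.frame with the needed columns, `follow_up_weeks` and `event`).
#' @param exposure Name of the exposure score column (e.g. `"dii"`).
#' @param exposure_type `"quartile"` or `"continuous"`.
#' @param tier Adjustment tier 1-3.
#' @param outcome Event label treated as the outcome (default `"cld"`).
#' @param ties Partial-likelihood tie handling, `"efron"` (default) or
#'   `"breslow"`.
#' @param conf_level Wald confidence level, default 0.95.
#' @param ph_test If `TRUE` (default), attach the Schoenfeld
#'   proportional-hazards test.
#' @return An object of class `dii_cox`: hazard-ratio table(s), trend p
#'   (quartile exposure), event count, PH test, and the underlying
#'   `survival::coxph` fit.
#' @export
fit_cox <- function(cohort, exposure = "dii",
                    exposure_type = c("quartile", "continuous"),
                    tier = 3, outcome = "cld",
                    ties = c("efron", "breslow"),
                    conf_level = 0.95, ph_test = TRUE) {
  exposure_type <- match.arg(exposure_type)
  ties <- match.arg(ties)
  mf <- build_model_frame(cohort, exposure, exposure_type, tier, outcome)
  n_events <- sum(mf$data$.status)
  if (n_events == 0L)
    stop("no events: no '", outcome, "' events in the cohort")

  fit <- survival::coxph(model_formula(mf$covs), data = mf$data,
                         ties = ties, x = TRUE, y = TRUE)
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))
  is_expo <- grepl("^\\.expo", names(co))
  tab <- hr_table(co[is_expo], se[is_expo], conf_level)
  tab$term <- sub("^\\.expo", "", tab$term)
  if (exposure_type == "continuous") tab$term <- exposure

  out <- structure(list(
    exposure = exposure, exposure_type = exposure_type,
    tier = as.integer(tier), outcome = outcome,
    hr = tab, n = nrow(mf$data), n_events = n_events,
    conf_level = conf_level, fit = fit), class = "dii_cox")

  if (exposure_type == "quartile")
    out$trend_p <- tryCatch(
      as.numeric(trend_test(cohort, exposure = exposure, tier = tier,
                            outcome = outcome)),
      error = function(e) NA_real_)
  if (ph_test && n_events >= 2L)
    out$ph <- tryCatch(schoenfeld_ph_test(out), error = function(e) NULL)
  out
}

#' @export
print.dii_cox <- function(x, ...) {
  cat(sprintf("Cox PH model (tier %d): %s [%s] -> %s; %d events / %d subjects\n",
              x$tier, x$exposure, x$exposure_type, x$outcome, x$n_events, x$n))
  print(format(x$hr, digits = 4), ...)
  if (!is.null(x$trend_p)) cat(sprintf("P for trend: %.4g\n", x$trend_p))
  if (!is.null(x$ph))
    cat(sprintf("Schoenfeld global PH test p = %.4g\n", x$ph$global_p))
  invisible(x)
}

#' @export
summary.dii_cox <- function(object, ...) summary(object$fit, ...)

#' @export
coef.dii_cox <- function(object, ...) stats::coef(object$fit)

#' Quartile-median trend test
#'
#' Replaces each participant's quartile label with the within-cohort
#' median exposure of that quartile, refits the Cox model with this value
#' as a continuous covariate, and returns the Wald p-value of its
#' coefficient -- the conventional "P for trend" across exposure
#' quartiles.
#'
#' @inheritParams fit_cox
#' @return The trend p-value (numeric scalar) with attributes `coef`
#'   (log-HR per exposure unit) and `hr`.
#' @export
trend_test <- function(cohort, exposure = "dii", tier = 3, outcome = "cld",
                       ties = "efron") {
  qcol <- paste0(exposure, "_quartile")
  if (!qcol %in% names(cohort))
    stop("invalid input: cohort lacks quartile labels ('", qcol, "')")
  if (!exposure %in% names(cohort))
    stop("invalid input: cohort lacks exposure column '", exposure, "'")
  med <- tapply(cohort[[exposure]], cohort[[qcol]], stats::median)
  if (anyNA(med) || any(diff(med) <= 0))
    stop("invalid input: quartile medians are not strictly increasing ",
         "(degenerate exposure)")
  cohort$.trend <- as.numeric(med[as.character(cohort[[qcol]])])
  mf <- build_model_frame(cohort, ".trend", "continuous", tier, outcome)
  if (sum(mf$data$.status) == 0L)
    stop("no events: no '", outcome, "' events in the cohort")
  fit <- survival::coxph(model_formula(mf$covs), data = mf$data, ties = ties)
  b <- stats::coef(fit)[".expo"]
  se <- sqrt(diag(stats::vcov(fit)))[".expo"]
  p <- 2 * stats::pnorm(-abs(b / se))
  structure(as.numeric(p), coef = unname(b), hr = unname(exp(b)))
}

#' Restricted cubic spline basis
#'
#' Truncated-power natural (restricted) cubic spline basis: linear beyond
#' the boundary knots, with `k - 2` nonlinear columns for `k` knots, each
#' normalised by the squared knot range. The first column is the exposure
#' itself.
#'
#' @param x Numeric vector.
#' @param knots Strictly increasing knot locations, length >= 3.
#' @return Matrix with `length(knots) - 1` columns.
#' @export
rcs_basis <- function(x, knots) {
  k <- length(knots)
  if (k < 3L || any(diff(knots) <= 0))
    stop("invalid input: need >= 3 strictly increasing knots")
  tk <- knots[k]; tk1 <- knots[k - 1L]
  norm <- (knots[k] - knots[1L])^2
  pos3 <- function(u) pmax(u, 0)^3
  out <- matrix(0, length(x), k - 1L)
  out[, 1L] <- x
  for (j in seq_len(k - 2L)) {
    tj <- knots[j]
    out[, j + 1L] <- (pos3(x - tj) -
                      pos3(x - tk1) * (tk - tj) / (tk - tk1) +
                      pos3(x - tk) * (tk1 - tj) / (tk - tk1)) / norm
  }
  colnames(out) <- c("lin", paste0("nl", seq_len(k - 2L)))
  out
}

default_knot_quantiles <- function(nknots) {
  switch(as.character(nknots),
         "3" = c(0.10, 0.50, 0.90),
         "4" = c(0.05, 0.35, 0.65, 0.95),
         "5" = c(0.05, 0.275, 0.50, 0.725, 0.95),
         stop("invalid input: nknots must be 3, 4 or 5"))
}

#' Restricted-cubic-spline test of dose-response nonlinearity
#'
#' Expands the continuous exposure in a restricted cubic spline basis
#' (default 4 knots at the 5th/35th/65th/95th exposure percentiles), fits
#' a Cox model with the spline terms plus the tier covariates, and reports
#' two Wald tests: `overall_p` for all spline terms (any association) and
#' `nonlinear_p` for the nonlinear terms only (departure from linearity).
#'
#' @inheritParams fit_cox
#' @param nknots Number of knots, 3-5.
#' @param knots Optional explicit knot locations (overrides `nknots`).
#' @return An object of class `dii_rcs` with fields `knots`,
#'   `coefficients`, `overall_p`, `nonlinear_p` and the underlying fit.
#' @export
rcs_nonlinearity <- function(cohort, exposure = "dii", tier = 3,
                             outcome = "cld", nknots = 4, knots = NULL,
                             ties = "efron") {
  if (!exposure %in% names(cohort))
    stop("invalid input: cohort lacks exposure column '", exposure, "'")
  x <- cohort[[exposure]]
  if (is.null(knots))
    knots <- unname(stats::quantile(x, default_knot_quantiles(nknots)))
  if (length(unique(x)) < length(knots) || any(diff(knots) <= 0))
    stop("invalid input: too few distinct exposure values for ",
         length(knots), " knots")
  basis <- rcs_basis(x, knots)

  covs <- tier_covariates(tier)
  check_model_columns(cohort, covs)
  d <- data.frame(.time = cohort$follow_up_weeks,
                  .status = as.integer(cohort$event == outcome))
  bn <- paste0(".rcs_", colnames(basis))
  d[bn] <- as.data.frame(basis)
  d[covs] <- cohort[covs]
  if (sum(d$.status) == 0L)
    stop("no events: no '", outcome, "' events in the cohort")
  form <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                  paste(c(bn, covs), collapse = " + ")))
  fit <- survival::coxph(form, data = d, ties = ties)
  co <- stats::coef(fit); V <- stats::vcov(fit)
  spline_idx <- match(bn, names(co))
  nl_idx <- spline_idx[-1L]
  structure(list(exposure = exposure, knots = knots,
                 coefficients = co[spline_idx],
                 overall_p = wald_test(co, V, spline_idx)$p,
                 nonlinear_p = wald_test(co, V, nl_idx)$p,
                 fit = fit), class = "dii_rcs")
}

#' @export
print.dii_rcs <- function(x, ...) {
  cat(sprintf("Restricted cubic spline Cox fit for '%s' (%d knots)\n",
              x$exposure, length(x$knots)))
  cat("  knots:", paste(format(x$knots, digits = 4), collapse = ", "), "\n")
  cat(sprintf("  overall p = %.4g; nonlinear p = %.4g\n",
              x$overall_p, x$nonlinear_p))
  invisible(x)
}

#' Predicted hazard-ratio curve from a spline fit
#'
#' Hazard ratios along a grid of exposure values relative to a reference
#' exposure (default: the first knot region's median is not used; the
#' cohort median of the fitted exposure grid), for dose-response figure
#' export.
#'
#' @param object A `dii_rcs` fit.
#' @param grid Exposure values at which to evaluate (default 100 points
#'   over the knot range).
#' @param ref Reference exposure value (HR = 1), default the grid median.
#' @param ... Unused.
#' @return Data.frame with `exposure`, `hr`, `ci_low`, `ci_high`.
#' @export
predict.dii_rcs <- function(object, grid = NULL, ref = NULL, ...) {
  kn <- object$knots
  if (is.null(grid)) grid <- seq(min(kn), max(kn), length.out = 100L)
  if (is.null(ref)) ref <- stats::median(grid)
  B <- rcs_basis(c(ref, grid), kn)
  D <- sweep(B[-1L, , drop = FALSE], 2, B[1L, ], "-")
  co <- object$coefficients
  V <- stats::vcov(object$fit)[names(co), names(co)]
  eta <- drop(D %*% co)
  se <- sqrt(rowSums((D %*% V) * D))
  data.frame(exposure = grid, hr = exp(eta),
             ci_low = exp(eta - 1.96 * se), ci_high = exp(eta + 1.96 * se))
}

#' Schoenfeld-residual test of the proportional-hazards assumption
#'
#' Scaled Schoenfeld residuals are tested for association with a transform
#' of event time (default: Kaplan-Meier transform), per covariate and
#' globally.
#'
#' @param fit A `dii_cox`, `dii_finegray` or `survival::coxph` fit.
#' @param transform Time transform passed to [survival::cox.zph()].
#' @return An object of class `dii_phtest` with a per-term `table`
#'   (chisq, df, p) and `global_p`.
#' @export
schoenfeld_ph_test <- function(fit, transform = "km") {
  cx <- if (inherits(fit, c("dii_cox", "dii_finegray"))) fit$fit else fit
  if (!inherits(cx, "coxph"))
    stop("invalid input: need a fitted Cox model")
  if (cx$nevent < 2L)
    stop("insufficient events: Schoenfeld test needs at least 2 events")
  z <- survival::cox.zph(cx, transform = transform, global = TRUE)
  tab <- as.data.frame(z$table)
  names(tab) <- c("chisq", "df", "p")
  structure(list(table = tab,
                 global_p = tab["GLOBAL", "p"],
                 transform = transform), class = "dii_phtest")
}

#' @export
print.dii_phtest <- function(x, ...) {
  cat("Schoenfeld proportional-hazards test (transform:", x$transform, ")\n")
  print(format(x$table, digits = 4))
  invisible(x)
}

#' Weibull accelerated failure time model
#'
#' Maximum-likelihood AFT fit, log-linear in the exposure and tier
#' covariates. Coefficients are reported as time ratios (acceleration
#' factors): a time ratio below 1 means shorter event-free time per unit
#' of exposure. Used as the fallback when the proportional-hazards
#' assumption fails ([schoenfeld_ph_test()] global p < 0.05).
#'
#' @inheritParams fit_cox
#' @param dist Failure-time distribution: `"weibull"` (default),
#'   `"lognormal"` or `"loglogistic"`.
#' @param scale Fixed scale parameter (`0` = estimate it; `1` with the
#'   Weibull reduces to the exponential AFT).
#' @return An object of class `dii_aft` with a `time_ratio` table and the
#'   underlying `survival::survreg` fit.
#' @export
fit_aft <- function(cohort, exposure = "dii",
                    exposure_type = c("quartile", "continuous"),
                    tier = 3, outcome = "cld",
                    dist = c("weibull", "lognormal", "loglogistic"),
                    conf_level = 0.95, scale = 0) {
  exposure_type <- match.arg(exposure_type)
  dist <- match.arg(dist)
  mf <- build_model_frame(cohort, exposure, exposure_type, tier, outcome)
  if (sum(mf$data$.status) == 0L)
    stop("no events: no '", outcome, "' events in the cohort")
  fit <- survival::survreg(model_formula(mf$covs), data = mf$data, dist = dist,
                           scale = scale)
  if (is.null(fit$coefficients) || any(!is.finite(fit$coefficients)))
    stop("fitting error: AFT model did not converge")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))[seq_along(co)]
  is_expo <- grepl("^\\.expo", names(co))
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  tab <- data.frame(term = sub("^\\.expo", "", names(co)[is_expo]),
                    time_ratio = exp(co[is_expo]),
                    ci_low = exp(co[is_expo] - zq * se[is_expo]),
                    ci_high = exp(co[is_expo] + zq * se[is_expo]),
                    p = 2 * stats::pnorm(-abs(co[is_expo] / se[is_expo])),
                    row.names = NULL, stringsAsFactors = FALSE)
  if (exposure_type == "continuous") tab$term <- exposure
  structure(list(exposure = exposure, exposure_type = exposure_type,
                 tier = as.integer(tier), outcome = outcome, dist = dist,
                 time_ratio = tab, scale = fit$scale,
                 n_events = sum(mf$data$.status), fit = fit),
            class = "dii_aft")
}

#' @export
print.dii_aft <- function(x, ...) {
  cat(sprintf("%s AFT model (tier %d): %s [%s] -> %s; %d events\n",
              x$dist, x$tier, x$exposure, x$exposure_type, x$outcome,
              x$n_events))
  print(format(x$time_ratio, digits = 4))
  invisible(x)
}

#' Fine-Gray subdistribution hazard model
#'
#' Estimates the association between exposure and the cumulative incidence
#' of the primary event in the presence of competing events. Subjects who
#' experience a competing event remain in later risk sets with
#' inverse-probability-of-censoring weights G(t)/G(min(T_i, t)) from a
#' Kaplan-Meier fit of the censoring distribution (the standard 1999
#' formulation, covariate-free censoring model); the weighted Cox partial
#' likelihood is maximised and a robust sandwich variance is used for the
#' confidence intervals. The data expansion is done by
#' [survival::finegray()]. With no competing events the model reduces
#' exactly to the Cox model.
#'
#' @inheritParams fit_cox
#' @param primary_event Event label modelled (default `"cld"`).
#' @param competing_events Labels treated as competing risks.
#' @return An object of class `dii_finegray` with an `shr` table
#'   (subdistribution hazard ratios) and the weighted `coxph` fit.
#' @export
fit_fine_gray <- function(cohort, exposure = "dii",
                          exposure_type = c("quartile", "continuous"),
                          tier = 3, primary_event = "cld",
                          competing_events = c("cirrhosis", "liver_cancer",
                                               "death"),
                          conf_level = 0.95) {
  exposure_type <- match.arg(exposure_type)
  if (sum(cohort$event == primary_event) == 0L)
    stop("no events: no '", primary_event, "' events in the cohort")

  mf <- build_model_frame(cohort, exposure, exposure_type, tier,
                          outcome = primary_event)
  d <- mf$data
  ev <- as.character(cohort$event)
  ev[!ev %in% c(primary_event, competing_events)] <- "censored"
  d$.ev <- factor(ev, levels = c("censored", primary_event, competing_events))
  d$.status <- NULL
  d$.id <- seq_len(nrow(d))

  fg <- survival::finegray(
    stats::as.formula(paste("survival::Surv(.time, .ev) ~ . - .id")),
    data = d, etype = primary_event)
  form <- stats::as.formula(paste(
    "survival::Surv(fgstart, fgstop, fgstatus) ~",
    paste(c(".expo", mf$covs), collapse = " + "), "+ cluster(.id)"))
  fit <- survival::coxph(form, data = fg, weights = fg$fgwt, ties = "efron")
  co <- stats::coef(fit)
  se <- sqrt(diag(stats::vcov(fit)))   # robust variance when robust = TRUE
  is_expo <- grepl("^\\.expo", names(co))
  tab <- hr_table(co[is_expo], se[is_expo], conf_level)
  names(tab)[names(tab) == "hr"] <- "shr"
  tab$term <- sub("^\\.expo", "", tab$term)
  if (exposure_type == "continuous") tab$term <- exposure
  structure(list(exposure = exposure, exposure_type = exposure_type,
                 tier = as.integer(tier), primary_event = primary_event,
                 competing_events = competing_events, shr = tab,
                 n_events = sum(cohort$event == primary_event),
                 conf_level = conf_level, fit = fit),
            class = "dii_finegray")
}

#' @export
print.dii_finegray <- function(x, ...) {
  cat(sprintf(
    "Fine-Gray model (tier %d): %s [%s] -> %s (competing: %s); %d events\n",
    x$tier, x$exposure, x$exposure_type, x$primary_event,
    paste(x$competing_events, collapse = ", "), x$n_events))
  print(format(x$shr, digits = 4))
  invisible(x)
}

#' @export
coef.dii_finegray <- function(object, ...) stats::coef(object$fit)

#' Progression analysis among incident cases
#'
#' Restricts the analysis to participants with an incident primary-disease
#' event, resets the time origin to diagnosis, and fits a Cox model for
#' progression to a later outcome (e.g. cirrhosis or liver cancer). The
#' case table must carry `progression_weeks` (time from diagnosis) and
#' `progression_event`.
#'
#' @param cases Data.frame of incident cases (rows with the primary
#'   event), including exposure, covariates, `progression_weeks` and
#'   `progression_event`.
#' @param outcome Progression outcome label, `"cirrhosis"` or
#'   `"liver_cancer"`.
#' @inheritParams fit_cox
#' @return A `dii_cox` object for the progression outcome.
#' @export
progression_analysis <- function(cases, outcome = c("cirrhosis",
                                                    "liver_cancer"),
                                 exposure = "dii",
                                 exposure_type = c("continuous", "quartile"),
                                 tier = 3, ...) {
  outcome <- match.arg(outcome)
  exposure_type <- match.arg(exposure_type)
  if (is.null(cases) || nrow(cases) == 0L)
    stop("no events: empty case set")
  need <- c("progression_weeks", "progression_event")
  miss <- setdiff(need, names(cases))
  if (length(miss))
    stop("invalid input: case table lacks column(s): ",
         paste(miss, collapse = ", "))
  if (sum(cases$progression_event == outcome) == 0L)
    stop("no events: no case progressed to '", outcome, "'")
  cases$follow_up_weeks <- cases$progression_weeks
  cases$event <- cases$progression_event
  fit_cox(cases, exposure = exposure, exposure_type = exposure_type,
          tier = tier, outcome = outcome, ...)
}
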