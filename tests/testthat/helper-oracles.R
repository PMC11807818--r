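## Independent oracles and small simulators used across the suite. These
## re-derive expected values from first principles and stay independent of
## the package's implementation paths.

## Standard normal CDF by numerical integration of the density (oracle for
## the percentile transform; deliberately avoids pnorm).
phi_numint <- function(z) {
  vapply(z, function(zz)
    0.5 + stats::integrate(function(t) exp(-t^2 / 2) / sqrt(2 * pi),
                           0, zz, rel.tol = 1e-12)$value,
    numeric(1))
}

## Spreadsheet-style step-by-step DII recomputation for one participant.
dii_by_hand <- function(intake, ref) {
  total <- 0
  for (i in seq_len(nrow(ref))) {
    z <- (intake[[ref$parameter[i]]] - ref$global_mean[i]) / ref$global_sd[i]
    pct <- 2 * stats::pnorm(z) - 1
    total <- total + pct * ref$weight[i]
  }
  total
}

## Efron partial log-likelihood, vectorised over a grid of beta values.
efron_loglik <- function(beta, time, status, x) {
  ll <- numeric(length(beta))
  ex <- exp(outer(x, beta))
  for (t in sort(unique(time[status == 1]))) {
    D <- which(time == t & status == 1)
    R <- which(time >= t)
    d <- length(D)
    SR <- colSums(ex[R, , drop = FALSE])
    SD <- colSums(ex[D, , drop = FALSE])
    ll <- ll + colSums(outer(x[D], beta))
    for (l in seq_len(d) - 1) ll <- ll - log(SR - (l / d) * SD)
  }
  ll
}

## Two-stage grid search maximisation over [-8, 8].
grid_max <- function(f) {
  g <- seq(-8, 8, length.out = 4001)
  b0 <- g[which.max(f(g))]
  g2 <- seq(b0 - 0.01, b0 + 0.01, length.out = 4001)
  g2[which.max(f(g2))]
}

## Left-continuous Kaplan-Meier of the censoring distribution, G(t-).
km_censor_minus <- function(t, time, is_cens) {
  ct <- sort(unique(time[is_cens]))
  G <- 1
  for (s in ct[ct < t]) G <- G * (1 - sum(time == s & is_cens) / sum(time >= s))
  G
}

## Hand-written IPCW-weighted subdistribution partial log-likelihood
## (1999 formulation): competing-event subjects stay in later risk sets
## with weight G(t-)/G(T_j-); type: 1 primary, 2 competing, 0 censored.
fg_loglik <- function(beta, time, type, x) {
  is_cens <- type == 0
  ll <- numeric(length(beta))
  for (i in which(type == 1)) {
    t <- time[i]
    atrisk <- which(time >= t)
    comp <- which(type == 2 & time < t)
    w <- c(rep(1, length(atrisk)),
           vapply(comp, function(j)
             km_censor_minus(t, time, is_cens) /
               km_censor_minus(time[j], time, is_cens), numeric(1)))
    xs <- x[c(atrisk, comp)]
    ll <- ll + x[i] * beta - log(colSums(w * exp(outer(xs, beta))))
  }
  ll
}

## Minimal single-covariate survival frames for method-validation
## simulations (time-constant exponential hazard, administrative censoring).
sim_frame <- function(n, loghaz, lambda0 = 5e-4, censor = 650) {
  x <- stats::rnorm(n, 0, 1.75)
  t <- stats::rexp(n, lambda0 * exp(loghaz(x)))
  data.frame(dii = x, follow_up_weeks = pmin(t, censor),
             event = ifelse(t <= censor, "cld", "censored"),
             stringsAsFactors = FALSE)
}

## Exponential hazard whose covariate effect optionally reverses sign at
## time tau (proportional-hazards violation).
sim_ph <- function(n, beta, reverse = FALSE, lambda0 = 1e-3, censor = 650,
                   tau = 346) {
  x <- stats::rnorm(n)
  if (!reverse) {
    t <- stats::rexp(n, lambda0 * exp(beta * x))
  } else {
    t1 <- stats::rexp(n, lambda0 * exp(beta * x))
    t <- ifelse(t1 < tau, t1, tau + stats::rexp(n, lambda0 * exp(-beta * x)))
  }
  data.frame(dii = x, follow_up_weeks = pmin(t, censor),
             event = ifelse(t <= censor, "cld", "censored"),
             stringsAsFactors = FALSE)
}

## Random small reference tables / intake records for property tests.
random_reference <- function(k = 5) {
  data.frame(parameter = paste0("par", seq_len(k)),
             global_mean = stats::runif(k, 1, 300),
             global_sd = stats::runif(k, 0.5, 60),
             weight = stats::runif(k, -0.7, 0.7),
             stringsAsFactors = FALSE)
}
random_record <- function(ref, id = "p1") {
  rec <- as.data.frame(as.list(stats::setNames(
    pmax(ref$global_mean + stats::rnorm(nrow(ref), 0, 2 * ref$global_sd), 0),
    ref$parameter)))
  rec$participant_id <- id
  rec
}

## Classified covariate frame for fits that bypass build_cohort.
classify_covariates <- function(cov) {
  cov$age_group <- dichotomize(cov$age, 58, c("younger", "older"))
  cov$tdi_group <- dichotomize(cov$tdi, -2.3, c("low", "high"),
                               boundary = "lower")
  cov$education <- reclassify_education(cov$education_code)
  cov$bp_category <- classify_bp(cov$systolic, cov$diastolic)
  cov
}
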