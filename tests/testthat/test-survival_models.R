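test_that("null and two-group exponential hazards are recovered", {
  set.seed(31)
  d0 <- sim_frame(50000, function(x) 0 * x)
  f0 <- fit_cox(d0, "dii", "continuous", tier = 1, ph_test = FALSE)
  expect_gt(f0$hr$hr, 0.98); expect_lt(f0$hr$hr, 1.02)

  set.seed(32)
  x <- rbinom(20000, 1, 0.5)
  t <- rexp(20000, 1e-3 * ifelse(x == 1, 2, 1))
  d2 <- data.frame(dii = x, follow_up_weeks = pmin(t, 650),
                   event = ifelse(t <= 650, "cld", "censored"))
  f2 <- fit_cox(d2, "dii", "continuous", tier = 1, ph_test = FALSE)
  expect_gt(f2$hr$hr, 1.9); expect_lt(f2$hr$hr, 2.1)
  expect_true(f2$hr$ci_low <= f2$hr$hr && f2$hr$hr <= f2$hr$ci_high)
})

test_that("a tiny all-events dataset matches the brute-force partial likelihood", {
  # interleaved covariate keeps the partial likelihood maximum finite
  d <- data.frame(dii = c(1, 0, 1, 0), follow_up_weeks = 1:4,
                  event = rep("cld", 4))
  f <- fit_cox(d, "dii", "continuous", tier = 1, ph_test = FALSE)
  b_oracle <- grid_max(function(b) efron_loglik(b, 1:4, rep(1, 4), c(1, 0, 1, 0)))
  expect_equal(unname(coef(f)[".expo"]), b_oracle, tolerance = 1e-4)
})

test_that("degenerate inputs raise the documented errors", {
  d <- sim_frame(200, function(x) 0 * x)
  d$event <- "censored"
  expect_error(fit_cox(d, "dii", "continuous", tier = 1), "no events")
  set.seed(33)
  d2 <- sim_frame(300, function(x) 0 * x)
  d2$age <- 50; d2$sex <- "female"; d2$ethnicity <- "white"
  d2$education <- "high"; d2$tdi <- rnorm(300)
  expect_error(fit_cox(d2, "dii", "continuous", tier = 2), "'age'")
})

test_that("quartile fits report Q1-referenced HRs and a trend p", {
  set.seed(34)
  d <- sim_frame(20000, function(x) 0.12 * x, lambda0 = 1e-3)
  d$dii_quartile <- assign_quartiles(d$dii)
  f <- fit_cox(d, "dii", "quartile", tier = 1, ph_test = FALSE)
  expect_equal(f$hr$term, c("Q2", "Q3", "Q4"))
  expect_true(all(f$hr$ci_low <= f$hr$hr & f$hr$hr <= f$hr$ci_high))
  expect_gt(f$hr$hr[3], 1)
  expect_lt(f$trend_p, 0.001)
  # trend and continuous fits agree in sign
  fc <- fit_cox(d, "dii", "continuous", tier = 1, ph_test = FALSE)
  expect_gt(fc$hr$hr, 1)
  expect_gt(attr(trend_test(d, "dii", tier = 1), "coef"), 0)
})

test_that("trend test rejects degenerate quartile medians", {
  d <- data.frame(dii = rep(1, 40), follow_up_weeks = runif(40, 60, 600),
                  event = sample(c("cld", "censored"), 40, TRUE),
                  dii_quartile = factor(rep(paste0("Q", 1:4), 10)))
  expect_error(trend_test(d, "dii", tier = 1), "strictly increasing")
  expect_error(trend_test(d[, -4], "dii", tier = 1), "quartile labels")
})

test_that("restricted spline basis is linear at and below the first knot", {
  knots <- c(-1, 0, 1, 2)
  x <- seq(-3, -1, length.out = 20)
  B <- rcs_basis(x, knots)
  expect_equal(B[, 1], x)
  expect_true(all(B[, -1] == 0))
  # linear far beyond the last knot: second differences of predictor vanish
  xr <- seq(5, 9, length.out = 9)
  Br <- rcs_basis(xr, knots)
  co <- c(1, 0.5, -0.3)
  eta <- drop(Br %*% co)
  expect_equal(max(abs(diff(diff(eta)))), 0, tolerance = 1e-10)
  expect_error(rcs_basis(x, c(1, 1, 2)), "strictly increasing")
})

test_that("spline fit flags a quadratic dose-response but not a linear one", {
  set.seed(35)
  d_lin <- sim_frame(15000, function(x) 0.1 * x, lambda0 = 1e-3)
  r_lin <- rcs_nonlinearity(d_lin, "dii", tier = 1)
  expect_gt(r_lin$overall_p, 0) ; expect_lt(r_lin$overall_p, 1e-6)
  expect_gt(r_lin$nonlinear_p, 0.01)

  d_quad <- sim_frame(15000, function(x) 0.06 * x^2, lambda0 = 1e-3)
  r_quad <- rcs_nonlinearity(d_quad, "dii", tier = 1)
  expect_lt(r_quad$nonlinear_p, 0.01)
  expect_equal(length(r_quad$knots), 4L)
  expect_error(rcs_nonlinearity(data.frame(dii = rep(1, 50)), "dii", tier = 1),
               "distinct")
})

test_that("spline predictions export a hazard-ratio curve around a reference", {
  set.seed(36)
  d <- sim_frame(8000, function(x) 0.1 * x, lambda0 = 1e-3)
  r <- rcs_nonlinearity(d, "dii", tier = 1)
  curve <- predict(r)
  expect_equal(nrow(curve), 100L)
  expect_true(all(curve$ci_low <= curve$hr & curve$hr <= curve$ci_high))
  ref <- median(curve$exposure)
  expect_equal(curve$hr[which.min(abs(curve$exposure - ref))], 1,
               tolerance = 0.05)
})

test_that("Schoenfeld test is well behaved for a single covariate", {
  set.seed(37)
  d <- sim_ph(5000, 0.3)
  f <- fit_cox(d, "dii", "continuous", tier = 1, ph_test = FALSE)
  z <- schoenfeld_ph_test(f)
  expect_equal(z$table["GLOBAL", "p"], z$table[".expo", "p"], tolerance = 1e-10)
  expect_true(z$global_p > 0 && z$global_p < 1)
  d1 <- d[1:3, ]; d1$event <- c("cld", "censored", "censored")
  one_event_fit <- suppressWarnings(survival::coxph(
    survival::Surv(follow_up_weeks, event == "cld") ~ dii, data = d1))
  expect_error(schoenfeld_ph_test(one_event_fit), "at least 2")
})

test_that("Weibull AFT recovers a known acceleration factor", {
  set.seed(38)
  n <- 20000
  x <- rnorm(n)
  # log T = log(T0) + log(0.8) * x, Weibull baseline
  t <- exp(log(rweibull(n, shape = 1.4, scale = 500)) + log(0.8) * x)
  d <- data.frame(dii = x, follow_up_weeks = pmin(t, 650),
                  event = ifelse(t <= 650, "cld", "censored"))
  f <- fit_aft(d, "dii", "continuous", tier = 1)
  expect_gt(f$time_ratio$time_ratio, 0.78)
  expect_lt(f$time_ratio$time_ratio, 0.82)

  set.seed(39)
  d0 <- sim_frame(20000, function(x) 0 * x, lambda0 = 1e-3)
  f0 <- fit_aft(d0, "dii", "continuous", tier = 1)
  expect_equal(f0$time_ratio$time_ratio, 1, tolerance = 0.05)
})

test_that("shape-fixed Weibull AFT reduces to the exponential model", {
  set.seed(40)
  d <- sim_frame(4000, function(x) 0.2 * x, lambda0 = 1e-3)
  f1 <- fit_aft(d, "dii", "continuous", tier = 1, scale = 1)
  f_exp <- survival::survreg(
    survival::Surv(follow_up_weeks, event == "cld") ~ dii, data = d,
    dist = "exponential")
  expect_equal(unname(coef(f1$fit)[".expo"]),
               unname(coef(f_exp)["dii"]), tolerance = 1e-3)
})

test_that("Fine-Gray equals Cox without competing events and handles no censoring", {
  set.seed(41)
  cfg <- sim_config(n = 4000, seed = 41, missing_rate = 0,
                    baseline_rates = c(cld = 1e-4, cirrhosis = 0,
                                       liver_cancer = 0, death = 0))
  raw <- generate_cohort(cfg)
  coh <- merge(raw$covariates, raw$followup, by = "participant_id")
  coh$dii <- raw$dii
  coh <- classify_covariates(coh)
  fg <- fit_fine_gray(coh, "dii", "continuous", tier = 2)
  cx <- fit_cox(coh, "dii", "continuous", tier = 2, ph_test = FALSE)
  expect_equal(unname(coef(fg)[".expo"]), unname(coef(cx)[".expo"]),
               tolerance = 1e-6)

  # no censoring: every subject observed to an event; weights are all one, so
  # the fit matches retaining competing subjects at full weight forever
  set.seed(42)
  n <- 300
  x <- rnorm(n)
  t1 <- rexp(n, 2e-3 * exp(0.3 * x)); t2 <- rexp(n, 1.5e-3)
  d <- data.frame(dii = x,
                  follow_up_weeks = pmin(t1, t2),
                  event = ifelse(t1 <= t2, "cld", "death"))
  fg2 <- fit_fine_gray(d, "dii", "continuous", tier = 1,
                       competing_events = "death")
  d_ext <- d
  keep <- d_ext$event == "death"
  d_ext$follow_up_weeks[keep] <- max(d$follow_up_weeks) + 1
  d_ext$event[keep] <- "censored"
  cx2 <- survival::coxph(
    survival::Surv(follow_up_weeks, event == "cld") ~ dii, data = d_ext,
    ties = "efron")
  expect_equal(unname(coef(fg2)[".expo"]), unname(coef(cx2)["dii"]),
               tolerance = 1e-6)
  expect_error(fit_fine_gray(subset(d, event == "death"), "dii",
                             "continuous", tier = 1,
                             competing_events = "death"),
               "no events")
})

test_that("progression analysis resets the clock and recovers its effect", {
  set.seed(43)
  n <- 4000
  dii <- rnorm(n, 0, 1.75)
  cases <- data.frame(participant_id = paste0("c", 1:n), dii = dii)
  t <- rexp(n, 2.5e-4 * exp(0.104 * dii))
  cases$progression_weeks <- pmin(t, 520)
  cases$progression_event <- ifelse(t <= 520, "cirrhosis", "none")
  f <- progression_analysis(cases, "cirrhosis", tier = 1, ph_test = FALSE)
  expect_gt(f$hr$hr, 1.05); expect_lt(f$hr$hr, 1.18)

  # shifting the time origin leaves the HR invariant for exponential times
  cases2 <- cases; cases2$progression_weeks <- cases2$progression_weeks + 100
  f2 <- progression_analysis(cases2, "cirrhosis", tier = 1, ph_test = FALSE)
  expect_equal(unname(coef(f2)[".expo"]), unname(coef(f)[".expo"]),
               tolerance = 1e-10)

  none <- cases; none$progression_event <- "none"
  expect_error(progression_analysis(none, "cirrhosis", tier = 1), "no case")
  expect_error(progression_analysis(cases[0, ], "cirrhosis", tier = 1),
               "empty case set")
})
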