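test_that("blood-pressure categories match the clinical thresholds", {
  expect_equal(as.character(classify_bp(118, 76)), "normal")
  expect_equal(as.character(classify_bp(125, 78)), "elevated")
  expect_equal(as.character(classify_bp(118, 85)), "stage1")  # diastolic alone
  expect_equal(as.character(classify_bp(135, 70)), "stage1")
  expect_equal(as.character(classify_bp(125, 85)), "stage1")  # gap case
  expect_equal(as.character(classify_bp(115, 92)), "stage2")
  expect_equal(as.character(classify_bp(140, 70)), "stage2")
  expect_error(classify_bp(0, 80), "positive")
  expect_error(classify_bp(120, -5), "positive")
})

test_that("education codes collapse into the three tiers", {
  expect_equal(as.character(reclassify_education(1)), "high")
  expect_equal(as.character(reclassify_education(c(2, 5, 6))),
               rep("median", 3))
  expect_equal(as.character(reclassify_education(c(3, 4, 7, -3))),
               rep("low", 4))
  expect_error(reclassify_education(9), "unknown education code")
})

test_that("median splits use the documented boundary conventions", {
  expect_equal(as.character(dichotomize(c(57, 58), 58, c("younger", "older"))),
               c("younger", "older"))
  expect_equal(as.character(dichotomize(-3.0, -2.3, c("low", "high"),
                                        boundary = "lower")), "low")
  expect_equal(as.character(dichotomize(-2.3, -2.3, c("low", "high"),
                                        boundary = "lower")), "low")
  expect_warning(dichotomize(rep(5, 4), 5, c("a", "b")), "single group")
})

test_that("quartile assignment partitions by rank with remainder to Q1", {
  q <- assign_quartiles(1:8)
  expect_equal(as.character(q), rep(c("Q1", "Q2", "Q3", "Q4"), each = 2))
  # remainder spread over the first groups
  expect_equal(as.integer(table(assign_quartiles(1:9))), c(3L, 2L, 2L, 2L))
  expect_equal(as.integer(table(assign_quartiles(1:11))), c(3L, 3L, 3L, 2L))
  # monotone in score, regardless of input order
  set.seed(2)
  x <- rnorm(101)
  q <- assign_quartiles(x)
  expect_true(max(x[q == "Q1"]) <= min(x[q == "Q2"]))
  expect_true(max(x[q == "Q3"]) <= min(x[q == "Q4"]))
  expect_true(all(abs(diff(as.integer(table(q)))) <= 1))
  # ties share the quartile of their rank block
  expect_warning(qt <- assign_quartiles(rep(1, 8)), "identical")
  expect_true(all(qt == "Q1"))
  expect_error(assign_quartiles(1:3), "at least 4")
})

small_raw <- function(n = 12, seed = 4) {
  set.seed(seed)
  ref <- dii_reference()
  intk <- as.data.frame(sapply(seq_len(nrow(ref)), function(j)
    pmax(ref$global_mean[j] + rnorm(n, 0, ref$global_sd[j]), 0.01)))
  names(intk) <- ref$parameter
  intakes <- cbind(data.frame(participant_id = paste0("p", 1:n)), intk)
  intakes$total_energy_kcal <- intakes$energy_kcal
  covariates <- data.frame(
    participant_id = paste0("p", 1:n),
    age = sample(45:70, n, TRUE), sex = sample(c("female", "male"), n, TRUE),
    ethnicity = sample(c("white", "others"), n, TRUE),
    education_code = sample(c(1:7, -3), n, TRUE),
    tdi = rnorm(n, -2, 3), bmi = runif(n, 20, 35),
    smoking = sample(c("rare", "previous", "current"), n, TRUE),
    alcohol = sample(c("rare", "previous", "current"), n, TRUE),
    physical_activity = sample(c("reach", "no-reach"), n, TRUE),
    systolic = sample(110:180, n, TRUE), diastolic = sample(60:100, n, TRUE),
    diabetes = sample(c("no", "yes"), n, TRUE),
    stringsAsFactors = FALSE)
  covariates$diastolic <- pmin(covariates$diastolic, covariates$systolic - 5)
  followup <- data.frame(participant_id = paste0("p", 1:n),
                         follow_up_weeks = runif(n, 60, 640),
                         event = sample(c("censored", "cld"), n, TRUE),
                         stringsAsFactors = FALSE)
  list(intakes = intakes, covariates = covariates, followup = followup)
}

test_that("landmark excludes early events and keeps later ones", {
  raw <- small_raw()
  raw$followup$follow_up_weeks[1] <- 40; raw$followup$event[1] <- "cld"
  raw$followup$follow_up_weeks[2] <- 60; raw$followup$event[2] <- "cld"
  res <- apply_exclusions(raw$intakes, raw$covariates, raw$followup)
  expect_true("p1" %in% res$log$participant_id)
  expect_equal(res$log$reason[res$log$participant_id == "p1"], "landmark")
  expect_true("p2" %in% res$cohort$participant_id)
  # boundary: exactly at the landmark is retained
  raw$followup$follow_up_weeks[3] <- 365.25 / 7
  res <- apply_exclusions(raw$intakes, raw$covariates, raw$followup)
  expect_true("p3" %in% res$cohort$participant_id)
})

test_that("exclusions log one reason per row with the documented precedence", {
  raw <- small_raw()
  raw$intakes$fibre_g[4] <- NA                       # missing nutrient
  raw$covariates$prior_cld <- FALSE
  raw$covariates$prior_cld[5] <- TRUE                # prior disease
  raw$followup$follow_up_weeks[5] <- 10              # ... also early event
  raw$followup$follow_up_weeks[6] <- 20              # landmark only
  res <- apply_exclusions(raw$intakes, raw$covariates, raw$followup)
  lg <- res$log
  expect_equal(lg$reason[lg$participant_id == "p4"], "missing-data")
  expect_equal(lg$reason[lg$participant_id == "p5"], "prior-disease")
  expect_equal(lg$reason[lg$participant_id == "p6"], "landmark")
  expect_equal(nrow(res$cohort) + nrow(lg), nrow(raw$intakes))
  expect_false(anyDuplicated(lg$participant_id) > 0)

  dup <- raw$intakes; dup$participant_id[2] <- "p1"
  expect_error(apply_exclusions(dup, raw$covariates, raw$followup),
               "duplicated participant_id")
})

test_that("empty input gives an empty cohort and log", {
  raw <- small_raw()
  res <- apply_exclusions(raw$intakes[0, ], raw$covariates[0, ],
                          raw$followup[0, ])
  expect_equal(nrow(res$cohort), 0L)
  expect_equal(nrow(res$log), 0L)
})

test_that("build_cohort yields scored, classified, quartiled rows", {
  raw <- small_raw(n = 40, seed = 6)
  built <- build_cohort(raw$intakes, raw$covariates, raw$followup)
  coh <- built$cohort
  expect_true(all(c("dii", "edii", "dii_quartile", "age_group", "tdi_group",
                    "education", "bp_category") %in% names(coh)))
  expect_true(all(abs(diff(as.integer(table(coh$dii_quartile)))) <= 1))
  expect_true(all(coh$follow_up_weeks >= 365.25 / 7))
  expect_equal(nrow(coh) + nrow(built$exclusion_log), 40L)
})
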