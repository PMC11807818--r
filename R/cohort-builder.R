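#' Classify blood pressure into four clinical categories
#'
#' Standard clinical-guideline categories from systolic (SP) and diastolic
#' (DP) pressure: normal (SP < 120 and DP < 80), elevated (120 <= SP <= 129
#' and DP < 80), stage 1 hypertension (130 <= SP <= 139 or 80 <= DP <= 89,
#' not meeting stage 2), stage 2 hypertension (SP >= 140 or DP >= 90).
#' Every positive (SP, DP) pair maps to exactly one category.
#'
#' @param systolic,diastolic Positive pressures in mmHg (vectorised).
#' @return Factor with levels `normal`, `elevated`, `stage1`, `stage2`.
#' @export
#' @examples
#' classify_bp(c(118, 125, 118, 115), c(76, 78, 85, 92))
classify_bp <- function(systolic, diastolic) {
  if (any(!is.finite(systolic)) || any(!is.finite(diastolic)) ||
      any(systolic <= 0) || any(diastolic <= 0))
    stop("invalid input: blood pressures must be positive and finite")
  out <- ifelse(systolic >= 140 | diastolic >= 90, "stage2",
         ifelse(systolic >= 130 | diastolic >= 80, "stage1",
         ifelse(systolic >= 120, "elevated", "normal")))
  factor(out, levels = c("normal", "elevated", "stage1", "stage2"))
}

#' Reclassify an educational qualification code into three tiers
#'
#' Collapses the 7-level questionnaire coding into High (college or
#' university degree, code 1), Median (A/AS levels code 2, HND/HNC code 5,
#' other professional qualifications code 6) and Low (O-levels/GCSE code 3,
#' CSE code 4, none of the above code 7, and prefer-not-to-answer, coded
#' -3 per the questionnaire's sentinel convention). The source
#' questionnaire lists prefer-not-to-answer under code 3 as well, which
#' collides with O-levels; this implementation keeps -3 as the
#' prefer-not-to-answer sentinel and maps it to Low.
#'
#' @param code Integer code(s): 1-7 or -3.
#' @return Factor with levels `low`, `median`, `high`.
#' @export
reclassify_education <- function(code) {
  out <- rep(NA_character_, length(code))
  out[code %in% 1] <- "high"
  out[code %in% c(2, 5, 6)] <- "median"
  out[code %in% c(3, 4, 7, -3)] <- "low"
  if (anyNA(out))
    stop("invalid input: unknown education code(s): ",
         paste(unique(code[is.na(out)]), collapse = ", "))
  factor(out, levels = c("low", "median", "high"))
}

#' Split a continuous covariate at a cutoff
#'
#' Median dichotomisation used for age (cutoff 58 years, values at the
#' cutoff assigned to the upper group) and the Townsend deprivation index
#' (cutoff -2.3, values at the cutoff assigned to the lower group). The
#' boundary side is configurable because only the cutoffs, not the
#' boundary conventions, are prescribed.
#'
#' @param value Finite numeric vector.
#' @param cutoff Finite cutoff.
#' @param labels Length-2 character: labels for the lower and upper group.
#' @param boundary `"upper"` (value == cutoff joins the upper group) or
#'   `"lower"`.
#' @return Factor with levels `labels`. Warns if every value lands in one
#'   group.
#' @export
#' @examples
#' dichotomize(c(57, 58), 58, c("younger", "older"))          # younger, older
#' dichotomize(-3.0, -2.3, c("low", "high"), boundary = "lower") # low
dichotomize <- function(value, cutoff, labels = c("low", "high"),
                        boundary = c("upper", "lower")) {
  boundary <- match.arg(boundary)
  if (any(!is.finite(value)) || !is.finite(cutoff))
    stop("invalid input: value and cutoff must be finite")
  upper <- if (boundary == "upper") value >= cutoff else value > cutoff
  out <- factor(ifelse(upper, labels[2], labels[1]), levels = labels)
  if (length(unique(out[!is.na(out)])) < 2L && length(value) > 1L)
    warning("all values fall in a single group ('", as.character(out[1]), "')")
  out
}

#' Assign exposure quartiles by rank
#'
#' Rank-based partition into four ascending groups. With n = 4q + r
#' observations the first r groups receive one extra member (so Q1 gets
#' the extra member when n is 1 mod 4). Tied scores share the quartile of
#' the first rank in their tie block.
#'
#' @param scores Numeric vector, length >= 4.
#' @return Factor with levels `Q1`-`Q4`, same length as `scores`.
#' @export
#' @examples
#' table(assign_quartiles(1:8)) # 2 per quartile
assign_quartiles <- function(scores) {
  n <- length(scores)
  if (n < 4L)
    stop("invalid input: need at least 4 observations to form quartiles")
  if (any(!is.finite(scores)))
    stop("invalid input: scores must be finite")
  sizes <- rep(n %/% 4L, 4L)
  if (n %% 4L) sizes[seq_len(n %% 4L)] <- sizes[seq_len(n %% 4L)] + 1L
  upper <- cumsum(sizes)                       # last rank belonging to each group
  r <- rank(scores, ties.method = "min")       # tie block -> first rank in block
  q <- findInterval(r, c(1L, head(upper, -1L) + 1L))
  if (length(unique(scores)) == 1L)
    warning("all scores identical: every observation assigned to Q1")
  factor(paste0("Q", q), levels = paste0("Q", 1:4))
}

#' Apply inclusion/exclusion rules to the raw tables
#'
#' Drops participants with (1) missing required nutrient, covariate or
#' follow-up fields; (2) a prior chronic liver disease or malignancy flag;
#' (3) any follow-up event -- including censoring -- within the first-year
#' landmark window (365.25 days by default). Each dropped participant is
#' logged with exactly one reason, the first matching in that order.
#'
#' @param intakes,covariates,followup Raw tables keyed by
#'   `participant_id`. `followup` must have `follow_up_weeks` and `event`;
#'   `covariates` may carry logical `prior_cld` / `prior_malignancy`
#'   columns.
#' @param reference Reference table defining the required nutrient columns.
#' @param landmark_weeks Landmark duration; events strictly before it are
#'   excluded, events at or after it retained. Default 365.25/7 weeks.
#' @return A list with `cohort` (merged retained rows) and `log`
#'   (data.frame `participant_id`, `reason`).
#' @export
apply_exclusions <- function(intakes, covariates, followup,
                             reference = dii_reference(),
                             landmark_weeks = 365.25 / 7) {
  for (tb in list(intakes, covariates, followup))
    if (anyDuplicated(tb$participant_id))
      stop("invalid input: duplicated participant_id in an input table")

  merged <- merge(merge(intakes, covariates, by = "participant_id"),
                  followup, by = "participant_id")
  if (nrow(merged) == 0L)
    return(list(cohort = merged,
                log = data.frame(participant_id = character(0),
                                 reason = character(0))))

  required_cov <- intersect(
    c("age", "sex", "ethnicity", "education_code", "tdi", "bmi", "smoking",
      "alcohol", "physical_activity", "systolic", "diastolic", "diabetes"),
    names(merged))
  required <- c(intersect(reference$parameter, names(intakes)),
                setdiff(reference$parameter, names(intakes)), # flagged missing below
    required_cov, "follow_up_weeks", "event")
  miss_param <- setdiff(reference$parameter, names(merged))
  missing_row <- rep(length(miss_param) > 0, nrow(merged))
  for (col in intersect(required, names(merged)))
    missing_row <- missing_row | is.na(merged[[col]])

  prior <- rep(FALSE, nrow(merged))
  for (col in intersect(c("prior_cld", "prior_malignancy"), names(merged)))
    prior <- prior | (merged[[col]] %in% TRUE)

  landmark <- merged$follow_up_weeks < landmark_weeks

  reason <- rep(NA_character_, nrow(merged))
  reason[landmark] <- "landmark"
  reason[prior] <- "prior-disease"
  reason[missing_row] <- "missing-data"

  keep <- is.na(reason)
  list(cohort = merged[keep, , drop = FALSE],
       log = data.frame(participant_id = merged$participant_id[!keep],
                        reason = reason[!keep], stringsAsFactors = FALSE))
}

#' Build the analysis-ready cohort table
#'
#' Runs the full cohort-construction pipeline: exclusions and one-year
#' landmark ([apply_exclusions()]), DII and eDII scoring, optional
#' HEI-2020 and MEDS scoring (when the needed food-group columns are
#' present), covariate reclassification (education tiers, blood-pressure
#' categories, median splits of age and deprivation), and DII quartile
#' assignment.
#'
#' @inheritParams apply_exclusions
#' @param density_reference Optional density reference for the eDII (see
#'   [edii_score()]).
#' @param age_cutoff,tdi_cutoff Median splits for age (years) and Townsend
#'   deprivation index; defaults 58 and -2.3.
#' @param mode Percentile transform passed to [dii_score()].
#' @return A list with `cohort` (analysis-ready data.frame: scores,
#'   quartiles, classified covariates, follow-up) and `exclusion_log`.
#' @export
build_cohort <- function(intakes, covariates, followup,
                         reference = dii_reference(),
                         density_reference = NULL,
                         landmark_weeks = 365.25 / 7,
                         age_cutoff = 58, tdi_cutoff = -2.3,
                         mode = "normal") {
  excl <- apply_exclusions(intakes, covariates, followup,
                           reference = reference,
                           landmark_weeks = landmark_weeks)
  coh <- excl$cohort
  if (nrow(coh) == 0L)
    return(list(cohort = coh, exclusion_log = excl$log))

  coh$dii <- dii_score(coh, reference = reference, mode = mode)$dii
  if ("total_energy_kcal" %in% names(coh))
    coh$edii <- edii_score(coh, reference = reference,
                           density_reference = density_reference,
                           mode = mode)$edii

  hei_cols_ok <- all(c("total_fruits", "total_vegetables") %in% names(coh))
  if (hei_cols_ok)
    coh$hei2020 <- tryCatch(compute_hei2020(coh)$hei2020, error = function(e) NULL)
  if (all(c("vegetables", "legumes", "fruits_nuts", "cereals", "fish",
            "meat", "dairy", "alcohol_g") %in% names(coh)))
    coh$meds <- compute_meds(coh, sex = coh$sex)$meds

  coh$age_group <- dichotomize(coh$age, age_cutoff, c("younger", "older"),
                               boundary = "upper")
  coh$tdi_group <- dichotomize(coh$tdi, tdi_cutoff, c("low", "high"),
                               boundary = "lower")
  coh$education <- reclassify_education(coh$education_code)
  coh$bp_category <- classify_bp(coh$systolic, coh$diastolic)
  for (col in c("sex", "ethnicity", "smoking", "alcohol",
                "physical_activity", "diabetes"))
    if (col %in% names(coh)) coh[[col]] <- factor(coh[[col]])
  coh$dii_quartile <- assign_quartiles(coh$dii)
  if ("edii" %in% names(coh)) coh$edii_quartile <- assign_quartiles(coh$edii)

  list(cohort = coh, exclusion_log = excl$log)
}
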