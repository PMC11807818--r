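#' HEI-2020 component standards
#'
#' The 13-component Healthy Eating Index 2020 scoring standards. Adequacy
#' components score 0 at `min_standard` and full `max_points` at
#' `max_standard`; moderation components score full points at
#' `min_standard` and 0 at `max_standard`; between the two standards the
#' score is linearly interpolated. Units: `density` components are amounts
#' per 1,000 kcal (cup- or ounce-equivalents, grams for sodium),
#' `ratio` is the (MUFA + PUFA) / SFA ratio, `pct_energy` is percent of
#' total energy.
#'
#' @return A data.frame with columns `component`, `max_points`,
#'   `direction`, `unit`, `min_standard`, `max_standard`.
#' @export
hei_standards <- function() {
  data.frame(
    component = c("total_fruits", "whole_fruits", "total_vegetables",
                  "greens_beans", "whole_grains", "dairy", "total_protein",
                  "seafood_plant_protein", "fatty_acid_ratio",
                  "refined_grains", "sodium_g", "added_sugars",
                  "saturated_fat"),
    max_points = c(5, 5, 5, 5, 10, 10, 5, 5, 10, 10, 10, 10, 10),
    direction = c(rep("adequacy", 9), rep("moderation", 4)),
    unit = c(rep("density", 8), "ratio", "density", "density",
             "pct_energy", "pct_energy"),
    min_standard = c(0, 0, 0, 0, 0, 0, 0, 0, 1.2, 1.8, 1.1, 6.5, 8),
    max_standard = c(0.8, 0.4, 1.1, 0.2, 1.5, 1.3, 2.5, 0.8, 2.5,
                    4.3, 2.0, 26, 16),
    stringsAsFactors = FALSE)
}

## Per-component exposure on the scale of the standards. Food-group columns
## carry daily amounts (cup/oz equivalents; grams for sodium); nutrient
## columns feed the ratio and percent-of-energy components.
hei_component_value <- function(intakes, component, unit, energy) {
  switch(unit,
    density = {
      if (!component %in% names(intakes))
        stop("missing data: intake table lacks food-group column ", component)
      intakes[[component]] * 1000 / energy
    },
    ratio = {
      need <- c("mufa_g", "pufa_g", "saturated_fat_g")
      miss <- setdiff(need, names(intakes))
      if (length(miss))
        stop("missing data: intake table lacks column(s): ",
             paste(miss, collapse = ", "))
      (intakes$mufa_g + intakes$pufa_g) / pmax(intakes$saturated_fat_g, 1e-12)
    },
    pct_energy = {
      col <- c(added_sugars = "added_sugars_g", saturated_fat = "saturated_fat_g")[[component]]
      kcal_per_g <- c(added_sugars = 4, saturated_fat = 9)[[component]]
      if (!col %in% names(intakes))
        stop("missing data: intake table lacks column ", col)
      intakes[[col]] * kcal_per_g * 100 / energy
    },
    stop("unknown unit: ", unit))
}

#' Score the Healthy Eating Index 2020
#'
#' Scores each participant's diet against the 13 HEI-2020 component
#' standards. Densities per 1,000 kcal (or ratios / percent of energy) are
#' linearly interpolated between the scoring standards and clamped to
#' `[0, max_points]`; adequacy components reward higher densities,
#' moderation components reward lower ones. The total ranges 0-100 and is,
#' by construction, invariant to proportional scaling of all intakes and
#' energy.
#'
#' @param intakes Data.frame with `participant_id`, `total_energy_kcal`,
#'   food-group columns named after the density components of
#'   [hei_standards()] (daily cup/oz equivalents, grams for `sodium_g`),
#'   and nutrient columns `mufa_g`, `pufa_g`, `saturated_fat_g`,
#'   `added_sugars_g`.
#' @param standards Standards table, default [hei_standards()].
#' @param detail If `TRUE`, attach the per-component score matrix as
#'   attribute `"component"`.
#' @return Data.frame with columns `participant_id` and `hei2020` in
#'   \[0, 100\].
#' @export
compute_hei2020 <- function(intakes, standards = hei_standards(), detail = FALSE) {
  if (!"participant_id" %in% names(intakes))
    stop("invalid input: intakes must have a participant_id column")
  if (!"total_energy_kcal" %in% names(intakes))
    stop("invalid input: intakes must have a total_energy_kcal column")
  energy <- intakes$total_energy_kcal
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("invalid input: total_energy_kcal must be strictly positive")
  stopifnot(sum(standards$max_points) == 100, nrow(standards) == 13L)

  scores <- matrix(NA_real_, nrow(intakes), nrow(standards),
                   dimnames = list(NULL, standards$component))
  for (i in seq_len(nrow(standards))) {
    s <- standards[i, ]
    v <- hei_component_value(intakes, s$component, s$unit, energy)
    frac <- (v - s$min_standard) / (s$max_standard - s$min_standard)
    if (s$direction == "moderation") frac <- 1 - frac
    scores[, i] <- s$max_points * pmin(pmax(frac, 0), 1)
  }
  out <- data.frame(participant_id = intakes$participant_id,
                    hei2020 = rowSums(scores), stringsAsFactors = FALSE)
  if (detail) attr(out, "component") <- scores
  out
}

#' Mediterranean Diet Score configuration
#'
#' Nine components: six beneficial (scored 1 at or above the cohort
#' median), two detrimental (scored 1 below the median), and alcohol
#' (scored 1 inside a moderate-intake range, by default 5-25 g/day for
#' both sexes -- an assumption, configurable here).
#'
#' @param alcohol_range Length-2 numeric, grams/day bounds of moderate
#'   alcohol intake.
#' @return A data.frame with columns `component`, `direction`, `lower`,
#'   `upper`.
#' @export
meds_config <- function(alcohol_range = c(5, 25)) {
  stopifnot(length(alcohol_range) == 2L, alcohol_range[1] < alcohol_range[2])
  data.frame(
    component = c("vegetables", "legumes", "fruits_nuts", "cereals",
                  "fish", "mufa_sfa_ratio", "meat", "dairy", "alcohol_g"),
    direction = c(rep("beneficial", 6), "detrimental", "detrimental", "range"),
    lower = c(rep(NA_real_, 8), alcohol_range[1]),
    upper = c(rep(NA_real_, 8), alcohol_range[2]),
    stringsAsFactors = FALSE)
}

#' Score adherence to the Mediterranean diet (MEDS)
#'
#' One point per beneficial component with intake at or above the cohort
#' median, one point per detrimental component with intake below the
#' median, and one point for alcohol intake inside the configured moderate
#' range; total 0-9. Medians are computed within the scored cohort,
#' sex-specifically when `sex` is supplied.
#'
#' @param intakes Data.frame with `participant_id` and one column per
#'   component of `config` (daily amounts; `mufa_sfa_ratio` may instead be
#'   derived from `mufa_g` and `saturated_fat_g` if absent).
#' @param config Component configuration, default [meds_config()].
#' @param sex Optional factor/character vector (one per row) for
#'   sex-specific median cutoffs.
#' @return Data.frame with columns `participant_id` and `meds` (integer
#'   0-9).
#' @export
compute_meds <- function(intakes, config = meds_config(), sex = NULL) {
  if (!"participant_id" %in% names(intakes))
    stop("invalid input: intakes must have a participant_id column")
  n <- nrow(intakes)
  if (n < 2L)
    stop("invalid configuration: cohort-median cutoffs need at least 2 participants")
  if (!is.null(sex) && length(sex) != n)
    stop("invalid input: sex must have one value per participant")
  if (!"mufa_sfa_ratio" %in% names(intakes) &&
      all(c("mufa_g", "saturated_fat_g") %in% names(intakes)))
    intakes$mufa_sfa_ratio <- intakes$mufa_g / pmax(intakes$saturated_fat_g, 1e-12)

  miss <- setdiff(config$component, names(intakes))
  if (length(miss))
    stop("missing data: intake table lacks component column(s): ",
         paste(miss, collapse = ", "))

  grp <- if (is.null(sex)) rep("all", n) else as.character(sex)
  pts <- matrix(0L, n, nrow(config), dimnames = list(NULL, config$component))
  for (i in seq_len(nrow(config))) {
    comp <- config$component[i]
    v <- intakes[[comp]]
    if (config$direction[i] == "range") {
      pts[, i] <- as.integer(v >= config$lower[i] & v <= config$upper[i])
    } else {
      med <- stats::ave(v, grp, FUN = stats::median)
      pts[, i] <- if (config$direction[i] == "beneficial")
        as.integer(v >= med) else as.integer(v < med)
    }
  }
  data.frame(participant_id = intakes$participant_id,
             meds = as.integer(rowSums(pts)), stringsAsFactors = FALSE)
}
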