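#' Default Dietary Inflammatory Index reference table
#'
#' Returns the reference table used to standardise nutrient intakes before
#' scoring: one row per dietary parameter with its global mean daily intake,
#' the global standard deviation of intake, and the literature-derived
#' inflammatory effect weight (negative = anti-inflammatory, positive =
#' pro-inflammatory).
#'
#' The shipped table covers 29 parameters typically available from an online
#' 24-hour dietary recall instrument. The means, SDs and weights are
#' literature-derived placeholder values in the style of the original DII
#' global reference database; studies with their own reference database
#' should replace the table via [read_dii_reference()].
#'
#' @return A data.frame with columns `parameter`, `global_mean`, `global_sd`
#'   and `weight`.
#' @seealso [dii_score()], [read_dii_reference()]
#' @export
#' @examples
#' head(dii_reference())
dii_reference <- function() {
  tab <- data.frame(
    parameter = c(
      "energy_kcal", "carbohydrate_g", "protein_g", "total_fat_g",
      "saturated_fat_g", "mufa_g", "pufa_g", "omega3_g", "omega6_g",
      "trans_fat_g", "cholesterol_mg", "fibre_g", "vitamin_a_re",
      "vitamin_b6_mg", "vitamin_b12_ug", "vitamin_c_mg", "vitamin_d_ug",
      "vitamin_e_mg", "folate_ug", "iron_mg", "magnesium_mg", "zinc_mg",
      "selenium_ug", "niacin_mg", "riboflavin_mg", "thiamin_mg",
      "caffeine_g", "alcohol_g", "tea_g"),
    global_mean = c(
      2056, 272.2, 79.4, 71.4,
      28.6, 27.0, 13.88, 1.06, 10.8,
      3.15, 279.4, 18.8, 983.9,
      1.47, 5.15, 118.2, 6.26,
      8.73, 273.0, 13.35, 310.1, 9.84,
      67.0, 25.9, 1.70, 1.70,
      8.05, 13.98, 1.69),
    global_sd = c(
      338, 40.0, 13.9, 19.4,
      8.0, 6.1, 3.76, 1.06, 4.27,
      3.75, 51.2, 4.9, 518.6,
      0.74, 2.70, 43.46, 2.21,
      1.49, 70.7, 3.71, 139.4, 2.19,
      25.1, 11.77, 0.79, 0.66,
      6.67, 3.72, 1.53),
    weight = c(
      0.180, 0.097, 0.021, 0.298,
      0.373, -0.009, -0.337, -0.436, -0.159,
      0.229, 0.110, -0.663, -0.401,
      -0.365, 0.106, -0.424, -0.446,
      -0.419, -0.190, 0.032, -0.484, -0.313,
      -0.191, -0.246, -0.068, -0.098,
      -0.110, -0.278, -0.536),
    stringsAsFactors = FALSE
  )
  validate_dii_reference(tab)
}

#' Read a DII reference table from CSV
#'
#' The file must have a header `parameter,global_mean,global_sd,weight`.
#' Use this to drop in a study-specific reference database in place of the
#' shipped defaults.
#'
#' @param path Path to a CSV file.
#' @return A validated reference data.frame (see [dii_reference()]).
#' @export
read_dii_reference <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  needed <- c("parameter", "global_mean", "global_sd", "weight")
  missing <- setdiff(needed, names(tab))
  if (length(missing))
    stop("invalid reference file: missing column(s) ",
         paste(missing, collapse = ", "))
  validate_dii_reference(tab[needed])
}

#' Validate a DII reference table
#'
#' Checks the structural invariants a reference table must satisfy:
#' at least one row, unique parameter names, finite means and weights,
#' strictly positive standard deviations.
#'
#' @param tab A data.frame with columns `parameter`, `global_mean`,
#'   `global_sd`, `weight`.
#' @return `tab`, invisibly unchanged, if valid; otherwise an error.
#' @export
validate_dii_reference <- function(tab) {
  if (!is.data.frame(tab) || nrow(tab) < 1L)
    stop("invalid reference: need a data.frame with at least one row")
  if (anyDuplicated(tab$parameter))
    stop("invalid reference: duplicated parameter name(s): ",
         paste(unique(tab$parameter[duplicated(tab$parameter)]), collapse = ", "))
  if (!all(is.finite(tab$global_mean)) || !all(is.finite(tab$weight)))
    stop("invalid reference: non-finite global_mean or weight")
  if (!all(is.finite(tab$global_sd)) || any(tab$global_sd <= 0))
    stop("invalid reference: global_sd must be strictly positive for every parameter")
  tab
}
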