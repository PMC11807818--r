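#' Standardise an intake against the global reference
#'
#' Z-score of an individual's mean daily intake relative to the global mean
#' and SD of the reference population.
#'
#' @param intake Numeric intake (parameter-specific units per day).
#' @param global_mean Global reference mean, same units.
#' @param global_sd Global reference SD, strictly positive.
#' @return `(intake - global_mean) / global_sd`, vectorised.
#' @export
#' @examples
#' dii_z(70, 50, 10) # 2
dii_z <- function(intake, global_mean, global_sd) {
  if (any(!is.finite(global_sd)) || any(global_sd <= 0))
    stop("invalid reference: global_sd must be strictly positive")
  (intake - global_mean) / global_sd
}

#' Convert a Z-score to a centered percentile
#'
#' Maps a Z-score to the doubled standard-normal CDF minus one,
#' `2 * pnorm(z) - 1`, which lies strictly inside (-1, 1) and is the
#' conventional percentile transform of DII scoring.
#'
#' @param z Finite numeric Z-score(s).
#' @return Centered percentile(s) in (-1, 1).
#' @export
#' @examples
#' dii_percentile(0)        # 0
#' dii_percentile(1.959964) # ~0.95
dii_percentile <- function(z) {
  if (any(!is.finite(z)))
    stop("invalid input: z must be finite")
  2 * stats::pnorm(z) - 1
}

## Empirical alternative to the normal-CDF percentile: centered rank
## transform 2 * (rank - 0.5)/n - 1, computed within the scored cohort.
empirical_centered_percentile <- function(x) {
  n <- length(x)
  2 * ((rank(x, ties.method = "average") - 0.5) / n) - 1
}

#' Score the Dietary Inflammatory Index
#'
#' Computes the DII for each participant: per parameter, the intake is
#' standardised against the global reference ([dii_z()]), converted to a
#' centered percentile ([dii_percentile()]), multiplied by the parameter's
#' inflammatory weight, and the weighted percentiles are summed.
#'
#' @param intakes A data.frame with a `participant_id` column and one
#'   numeric column per reference parameter (mean daily intake).
#' @param reference A reference table as returned by [dii_reference()].
#' @param mode Percentile transform: `"normal"` (default, doubled normal
#'   CDF) or `"empirical"` (centered cohort rank transform).
#' @param detail If `TRUE`, attach per-parameter Z-scores, centered
#'   percentiles and component scores as attributes `"z"`,
#'   `"percentile"` and `"component"` (matrices, participants x parameters).
#' @return An object of class `dii_scores`: a data.frame with columns
#'   `participant_id` and `dii`.
#' @export
#' @examples
#' ref <- dii_reference()
#' at_mean <- as.data.frame(as.list(stats::setNames(ref$global_mean, ref$parameter)))
#' at_mean$participant_id <- "p1"
#' dii_score(at_mean)$dii # 0
dii_score <- function(intakes, reference = dii_reference(),
                      mode = c("normal", "empirical"), detail = FALSE) {
  mode <- match.arg(mode)
  reference <- validate_dii_reference(reference)
  if (!"participant_id" %in% names(intakes))
    stop("invalid input: intakes must have a participant_id column")
  missing <- setdiff(reference$parameter, names(intakes))
  if (length(missing))
    stop("missing data: intake table lacks parameter(s): ",
         paste(missing, collapse = ", "))
  x <- as.matrix(intakes[reference$parameter])
  if (!is.numeric(x) || any(!is.finite(x)))
    stop("invalid input: intakes must be finite numerics for every parameter")
  if (any(x < 0))
    stop("invalid input: intakes must be non-negative")

  z <- sweep(sweep(x, 2, reference$global_mean, "-"), 2, reference$global_sd, "/")
  pct <- if (mode == "normal") 2 * stats::pnorm(z) - 1 else apply(z, 2, empirical_centered_percentile)
  if (is.null(dim(pct))) pct <- matrix(pct, nrow = nrow(z), dimnames = dimnames(z))
  comp <- sweep(pct, 2, reference$weight, "*")

  out <- data.frame(participant_id = intakes$participant_id,
                    dii = rowSums(comp), stringsAsFactors = FALSE)
  class(out) <- c("dii_scores", "data.frame")
  attr(out, "mode") <- mode
  attr(out, "index") <- "dii"
  if (detail) {
    attr(out, "z") <- z
    attr(out, "percentile") <- pct
    attr(out, "component") <- comp
  }
  out
}

#' Score the energy-adjusted Dietary Inflammatory Index (eDII)
#'
#' Normalises each nutrient intake by the density method (intake per
#' 1,000 kcal of total energy) and then applies the same standardise /
#' percentile / weight / sum steps as [dii_score()] against a density
#' reference table.
#'
#' When no external density reference is supplied, density means and SDs
#' are derived from the scored cohort itself (weights are taken from
#' `reference`); this fallback is appropriate for internal ranking but the
#' resulting scores are then relative to the cohort, not to a global
#' population.
#'
#' @param intakes As in [dii_score()], plus a positive `total_energy_kcal`
#'   column.
#' @param reference Absolute-intake reference table; supplies the weights
#'   (and the parameter list) for the cohort-derived fallback.
#' @param density_reference Optional reference table whose means/SDs are
#'   expressed per 1,000 kcal. If `NULL`, derived from the cohort.
#' @param mode,detail As in [dii_score()].
#' @return An object of class `dii_scores` with columns `participant_id`
#'   and `edii`.
#' @export
edii_score <- function(intakes, reference = dii_reference(),
                       density_reference = NULL,
                       mode = c("normal", "empirical"), detail = FALSE) {
  mode <- match.arg(mode)
  if (!"total_energy_kcal" %in% names(intakes))
    stop("invalid input: intakes must have a total_energy_kcal column")
  energy <- intakes$total_energy_kcal
  if (any(!is.finite(energy)) || any(energy <= 0))
    stop("invalid input: total_energy_kcal must be strictly positive")

  reference <- validate_dii_reference(reference)
  missing <- setdiff(reference$parameter, names(intakes))
  if (length(missing))
    stop("missing data: intake table lacks parameter(s): ",
         paste(missing, collapse = ", "))

  dens <- intakes
  dens[reference$parameter] <-
    sweep(as.matrix(intakes[reference$parameter]) * 1000, 1, energy, "/")

  if (is.null(density_reference)) {
    dmat <- as.matrix(dens[reference$parameter])
    density_reference <- data.frame(
      parameter = reference$parameter,
      global_mean = colMeans(dmat),
      global_sd = apply(dmat, 2, stats::sd),
      weight = reference$weight,
      stringsAsFactors = FALSE)
    if (any(!is.finite(density_reference$global_sd)) ||
        any(density_reference$global_sd <= 0))
      stop("invalid reference: cohort-derived density SDs are not all positive; ",
           "supply a density_reference (need >= 2 participants with varying densities)")
  }

  out <- dii_score(dens, reference = density_reference, mode = mode, detail = detail)
  names(out)[names(out) == "dii"] <- "edii"
  attr(out, "index") <- "edii"
  out
}

#' @export
print.dii_scores <- function(x, ...) {
  idx <- toupper(attr(x, "index") %||% "dii")
  cat(sprintf("%s scores for %d participants (%s percentile transform)\n",
              idx, nrow(x), attr(x, "mode") %||% "normal"))
  v <- x[[2L]]
  cat(sprintf("  range %.3f .. %.3f, mean %.3f\n", min(v), max(v), mean(v)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write per-participant scores to CSV
#'
#' @param x A `dii_scores` object (or any data.frame of scores).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_scores_csv <- function(x, path) {
  utils::write.csv(as.data.frame(x), path, row.names = FALSE)
  invisible(path)
}
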