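# Circulating T cell accounting: anthropometric blood volume (Nadler),
# per-subset cell totals from CBC lymphocyte counts and flow fractions,
# and the projection target used for richness extrapolation.

#' Total blood volume by Nadler's formula
#'
#' `male: 0.3669 h^3 + 0.03219 w + 0.6041`;
#' `female: 0.3561 h^3 + 0.03308 w + 0.1833`, with height `h` in meters
#' and weight `w` in kilograms.
#'
#' @param height Height; meters by default (`units = "cm"` accepts
#'   centimeters explicitly — the cubic height term makes silent unit
#'   mixups the main hazard here).
#' @param weight Weight in kg.
#' @param sex `"male"` or `"female"` (vectorized).
#' @param units Height units, `"m"` or `"cm"`.
#' @return Blood volume in liters.
#' @examples
#' nadler_volume(1.80, 80, "male")
#' @export
nadler_volume <- function(height, weight, sex, units = c("m", "cm")) {
  units <- match.arg(units)
  if (units == "cm") {
    height <- height / 100
  }
  if (any(height <= 0) || any(weight <= 0)) {
    stop("height and weight must be positive", call. = FALSE)
  }
  sex <- match.arg(sex, c("male", "female"), several.ok = TRUE)
  male <- sex == "male"
  ifelse(male,
         0.3669 * height^3 + 0.03219 * weight + 0.6041,
         0.3561 * height^3 + 0.03308 * weight + 0.1833)
}

#' Circulating cells of a subset in total blood
#'
#' `lymphocytes_per_ul x subset fraction x blood volume (in microliters)`.
#' The profile must carry `lymphocytes_per_ul`, `height_m`, `weight_kg`,
#' `sex`, and a `frac_<subset>` column (fraction of lymphocytes).
#'
#' @param profile A one-row data frame or named list (see
#'   [simulate_cohort()] profiles).
#' @param subset Subset name, e.g. `"CD4_naive"`.
#' @return Cell count in the donor's total blood (unrounded).
#' @export
subset_total <- function(profile, subset) {
  frac_col <- paste0("frac_", subset)
  if (!frac_col %in% names(profile) || is.na(profile[[frac_col]][1])) {
    stop("profile has no fraction for subset '", subset, "'", call. = FALSE)
  }
  volume_l <- nadler_volume(profile$height_m[1], profile$weight_kg[1],
                            profile$sex[1])
  profile$lymphocytes_per_ul[1] * profile[[frac_col]][1] * volume_l * 1e6
}

#' Projection target population for richness extrapolation
#'
#' Richness is extrapolated not to the full circulating population but to
#' a fixed fraction of it (1/100 by default), keeping the rarefaction
#' model extrapolation within a computable range. Rounding is
#' round-half-even, applied at this final step only.
#'
#' @param total_cells Circulating cell count (>= 1).
#' @param factor Scaling factor (> 0).
#' @return The rounded target population size.
#' @examples
#' projection_target(3e9)       # 3e7
#' projection_target(250)       # 2 (round-half-even)
#' @export
projection_target <- function(total_cells, factor = 1 / 100) {
  if (any(factor <= 0)) {
    stop("factor must be positive", call. = FALSE)
  }
  if (any(total_cells < 1)) {
    stop("total_cells must be >= 1", call. = FALSE)
  }
  round(total_cells * factor)
}
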