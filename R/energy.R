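#' Metabolisable-energy conversion factors
#'
#' Atwater-style factors (kJ per gram) used to convert nutrient masses into
#' their energy contribution when expressing intakes as percentage of total
#' energy (E%). National food-composition databases embed their own factors
#' in the tabulated energy values; these constants are only used on the
#' nutrient side of the E% ratio and are configurable.
#'
#' @param protein,carbohydrate,fat kJ per gram of the macronutrient.
#' @param sucrose kJ per gram; defaults to the carbohydrate factor.
#' @param fatty_acid kJ per gram for the fatty-acid classes (PUFA, MUFA,
#'   SFA); defaults to the fat factor.
#'
#' @return A named list of class `energy_factors`.
#' @examples
#' energy_factors()
#' energy_factors(fat = 38)
#' @export
energy_factors <- function(protein = 17, carbohydrate = 17, fat = 37,
                           sucrose = carbohydrate, fatty_acid = fat) {
  factors <- list(
    protein = protein, carbohydrate = carbohydrate, fat = fat,
    sucrose = sucrose, fatty_acid = fatty_acid
  )
  bad <- names(factors)[vapply(factors, function(x) !is.numeric(x) || x <= 0, logical(1))]
  if (length(bad)) {
    abort(paste0("Energy factors must be positive numbers: ", toString(bad)))
  }
  structure(factors, class = "energy_factors")
}

#' Percentage of total energy supplied by a nutrient
#'
#' @param nutrient_g Grams per day of the nutrient (vectorised).
#' @param factor_kj_per_g Energy factor of the nutrient, kJ/g.
#' @param energy_kj Total daily energy intake, kJ.
#'
#' @return E% values; `NA` where `energy_kj` is zero or missing (the ratio
#'   is undefined for an empty day, never a division by zero).
#' @examples
#' energy_percent(50, 17, 8500) # 10 E%
#' @export
energy_percent <- function(nutrient_g, factor_kj_per_g, energy_kj) {
  if (any(nutrient_g < 0, na.rm = TRUE)) {
    abort("`nutrient_g` must be non-negative.")
  }
  out <- 100 * nutrient_g * factor_kj_per_g / energy_kj
  out[!is.na(energy_kj) & energy_kj <= 0] <- NA_real_
  out
}

#' Energy-plausibility screening configuration
#'
#' Daily energy intakes above `high_kcal` or below `low_kcal` are flagged
#' for manual review. Thresholds are stored in kcal (the unit screening
#' protocols are written in) and compared after converting the day's kJ
#' total; flagged days are retained unless explicitly excluded downstream.
#'
#' @param low_kcal,high_kcal Screening thresholds in kcal/day.
#' @param kcal_to_kj Conversion factor, kJ per kcal.
#' @return A list of class `plausibility_config`.
#' @export
plausibility_config <- function(low_kcal = 800, high_kcal = 3500,
                                kcal_to_kj = 4.184) {
  stopifnot(low_kcal >= 0, high_kcal > low_kcal, kcal_to_kj > 0)
  structure(
    list(low_kcal = low_kcal, high_kcal = high_kcal, kcal_to_kj = kcal_to_kj),
    class = "plausibility_config"
  )
}

#' Flag implausible daily energy intakes
#'
#' A day is `"high"` when its energy intake strictly exceeds the upper
#' threshold, `"low"` when strictly below the lower threshold, `"ok"`
#' otherwise; a day at exactly 3500 kcal is `"ok"`.
#'
#' @param energy_kj Daily energy intake(s) in kJ.
#' @param cfg A [plausibility_config()].
#' @return Character vector in `{"ok", "low", "high"}`.
#' @examples
#' plausibility_flag(c(2000, 3600, 700) * 4.184)
#' @export
plausibility_flag <- function(energy_kj, cfg = plausibility_config()) {
  stopifnot(inherits(cfg, "plausibility_config"))
  if (any(energy_kj < 0, na.rm = TRUE)) abort("`energy_kj` must be non-negative.")
  kcal <- energy_kj / cfg$kcal_to_kj
  case_when(
    is.na(kcal) ~ NA_character_,
    kcal > cfg$high_kcal ~ "high",
    kcal < cfg$low_kcal ~ "low",
    TRUE ~ "ok"
  )
}
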