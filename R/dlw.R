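#' Physical and physiological constants for the DLW calculation
#'
#' One place for every named constant of the doubly-labelled-water chain:
#' the two-pool CO2-production equation, the isotope fractionation
#' multipliers, dose-water molar masses, the molar volume used to convert
#' mol/day to L/day, and the Weir-derived energy equivalent of CO2.
#'
#' The CO2 production rate is
#' \deqn{rCO_2 = N (f_O k_O - f_D k_D) (1/d - g_1 g_2)}
#' with pool size \eqn{N = (N_D / r + N_O) / 2}, where `pool_divisor` d =
#' 2.078, fractionation multipliers \eqn{f_O} = 1.007 and \eqn{f_D} = 1.041,
#' fractionated-water correction \eqn{g_1} = 0.0246 and breath-water
#' fraction \eqn{g_2} = 1.05, and `dsr_norm` r = 1.0427 the population
#' dilution-space-ratio normaliser. The energy equivalent of a litre of CO2
#' is \eqn{(a/FQ + b)} kcal/L with the Weir coefficients a = 3.941,
#' b = 1.106, converted to kJ.
#'
#' @param pool_divisor,frac_o,frac_d,frac_water,breath_frac,dsr_norm
#'   Two-pool equation coefficients (see above).
#' @param molar_mass_2h2o,molar_mass_h218o Molar masses (g/mol) used to turn
#'   dose grams into moles of labelled water.
#' @param molar_volume_l L of CO2 per mol.
#' @param weir_a,weir_b Weir coefficients, kcal per L of O2 and CO2.
#' @param kcal_to_kj kJ per kcal.
#' @param dsr_qc Length-2 numeric; dilution-space-ratio quality-control
#'   band (results outside it are flagged, not dropped).
#' @return A named list of class `dlw_constants`.
#' @export
dlw_constants <- function(pool_divisor = 2.078, frac_o = 1.007,
                          frac_d = 1.041, frac_water = 0.0246,
                          breath_frac = 1.05, dsr_norm = 1.0427,
                          molar_mass_2h2o = 18.02, molar_mass_h218o = 20.02,
                          molar_volume_l = 22.4, weir_a = 3.941,
                          weir_b = 1.106, kcal_to_kj = 4.184,
                          dsr_qc = c(1.00, 1.07)) {
  structure(
    list(
      pool_divisor = pool_divisor, frac_o = frac_o, frac_d = frac_d,
      frac_water = frac_water, breath_frac = breath_frac,
      dsr_norm = dsr_norm, molar_mass_2h2o = molar_mass_2h2o,
      molar_mass_h218o = molar_mass_h218o, molar_volume_l = molar_volume_l,
      weir_a = weir_a, weir_b = weir_b, kcal_to_kj = kcal_to_kj,
      dsr_qc = dsr_qc
    ),
    class = "dlw_constants"
  )
}

#' Fit isotope elimination rates from urine enrichment series
#'
#' For each participant and isotope, subtracts the baseline (the mean of the
#' pre-dose samples), and fits ordinary least squares of `ln(excess)` on
#' time since dose. The elimination rate is minus the slope; the zero-time
#' excess is the exponential of the intercept.
#'
#' @param urines Tibble with columns `participant_id`, `time_days`,
#'   `enr_2h`, `enr_18o`, `is_baseline`. Enrichments must be in one
#'   consistent unit per dataset (the unit cancels in the rate but not in
#'   the dilution space, so it must match the dose-enrichment unit).
#' @param isotope `"2H"`, `"18O"`, or both (default).
#' @return A tibble of class `elimination_fit`: `participant_id`, `isotope`,
#'   `k` (per day), `zero_time_excess`, `r_squared`, `n_points`. The
#'   baseline-subtracted points are attached as attribute `"points"` for
#'   plotting.
#' @examples
#' u <- tibble::tibble(
#'   participant_id = "p1",
#'   time_days = c(-1, 0, 1, 5, 8, 12, 15),
#'   enr_2h = c(0, 0, 150 * exp(-0.09 * c(1, 5, 8, 12, 15))),
#'   enr_18o = c(0, 0, 120 * exp(-0.11 * c(1, 5, 8, 12, 15))),
#'   is_baseline = c(TRUE, TRUE, rep(FALSE, 5))
#' )
#' fit_elimination(u)
#' @export
fit_elimination <- function(urines, isotope = c("2H", "18O")) {
  isotope <- match.arg(isotope, several.ok = TRUE)
  required <- c("participant_id", "time_days", "enr_2h", "enr_18o",
                "is_baseline")
  missing <- setdiff(required, names(urines))
  if (length(missing)) {
    abort(paste0("`urines` is missing column(s): ", toString(missing)))
  }
  enr_col <- c("2H" = "enr_2h", "18O" = "enr_18o")

  combos <- tidyr::expand_grid(
    participant_id = unique(urines$participant_id),
    isotope = isotope
  )
  points <- list()
  fits <- purrr::pmap_dfr(combos, function(participant_id, isotope) {
    pu <- urines[urines$participant_id == participant_id, ]
    col <- enr_col[[isotope]]
    base <- pu[pu$is_baseline, ]
    if (!nrow(base)) {
      abort(paste0("No baseline samples for participant ", participant_id))
    }
    baseline <- mean(base[[col]])
    post <- pu[!pu$is_baseline, ]
    excess <- post[[col]] - baseline
    if (any(excess <= 0)) {
      bad <- post$time_days[excess <= 0][1]
      abort(paste0(
        "Non-positive post-dose excess enrichment for participant ",
        participant_id, " (", isotope, ") at day ", bad,
        "; elimination kinetics undefined."
      ))
    }
    if (nrow(post) < 2) {
      abort(paste0("Need >= 2 post-dose samples for participant ",
                   participant_id, " (", isotope, ")."))
    }
    fit <- lm(log(excess) ~ post$time_days)
    ss_tot <- sum((log(excess) - mean(log(excess)))^2)
    r2 <- if (ss_tot > 0) 1 - sum(fit$residuals^2) / ss_tot else 1
    points[[length(points) + 1]] <<- tibble(
      participant_id = participant_id, isotope = isotope,
      time_days = post$time_days, excess = excess
    )
    tibble(
      participant_id = participant_id, isotope = isotope,
      k = -unname(coef(fit)[2]),
      zero_time_excess = exp(unname(coef(fit)[1])),
      r_squared = r2,
      n_points = nrow(post)
    )
  })
  structure(fits,
            points = dplyr::bind_rows(points),
            class = c("elimination_fit", class(fits)))
}

#' Isotope dilution space from dose and zero-time enrichment
#'
#' The apparent body-water pool (mol) diluting an isotope dose:
#' `N = dose_mol * dose_enrichment / zero_time_excess`, where `dose_mol` is
#' dose grams over the labelled water's molar mass. Dose and sample
#' enrichments must share one unit.
#'
#' @param dose_g Dose mass, g (vectorised).
#' @param dose_enrichment Enrichment of the dose water, same unit as the
#'   urine excess enrichments.
#' @param zero_time_excess Back-extrapolated excess enrichment at t = 0 from
#'   [fit_elimination()]; must be positive.
#' @param molar_mass g/mol of the dose water (18.02 for 2H2O as water
#'   equivalent, 20.02 for H2-18O).
#' @return Dilution space(s) in mol.
#' @export
dilution_space <- function(dose_g, dose_enrichment, zero_time_excess,
                           molar_mass) {
  if (any(dose_g <= 0) || any(dose_enrichment <= 0)) {
    abort("Dose mass and dose enrichment must be positive.")
  }
  if (any(zero_time_excess <= 0)) {
    abort("`zero_time_excess` must be positive (non-positive intercept).")
  }
  (dose_g / molar_mass) * dose_enrichment / zero_time_excess
}

#' CO2 production from the two-pool equation
#'
#' @param n_d,n_o Deuterium and oxygen-18 dilution spaces, mol.
#' @param k_d,k_o Elimination rates, per day.
#' @param constants [dlw_constants()].
#' @return CO2 production in mol/day. Errors when the fractionation-weighted
#'   rate difference `frac_o * k_o - frac_d * k_d` is not positive (oxygen
#'   must turn over faster than deuterium in physiological data).
#' @export
co2_production <- function(n_d, n_o, k_d, k_o, constants = dlw_constants()) {
  stopifnot(inherits(constants, "dlw_constants"))
  delta <- constants$frac_o * k_o - constants$frac_d * k_d
  if (any(delta < 0)) {
    abort(paste0(
      "Non-physiological rates: frac_o*k_o - frac_d*k_d must be positive ",
      "(oxygen is eliminated as water plus CO2 and must turn over faster)."
    ))
  }
  n_pool <- (n_d / constants$dsr_norm + n_o) / 2
  n_pool * delta *
    (1 / constants$pool_divisor -
       constants$frac_water * constants$breath_frac)
}

#' Energy equivalent of CO2 for a given food quotient
#'
#' Weir-derived energy released per litre of CO2 produced, given the diet's
#' food quotient (the respiratory quotient predicted from its macronutrient
#' composition): `(weir_a / FQ + weir_b)` kcal/L, converted to kJ/L.
#'
#' @param food_quotient Dimensionless, in `[0.7, 1.0]`.
#' @param constants [dlw_constants()].
#' @return kJ per litre of CO2.
#' @examples
#' energy_equivalent(0.86) # the typical mixed-diet operating point
#' @export
energy_equivalent <- function(food_quotient, constants = dlw_constants()) {
  stopifnot(inherits(constants, "dlw_constants"))
  if (any(food_quotient < 0.7 | food_quotient > 1.0)) {
    abort("`food_quotient` must lie in [0.7, 1.0].")
  }
  (constants$weir_a / food_quotient + constants$weir_b) * constants$kcal_to_kj
}

#' Total energy expenditure from doubly labelled water
#'
#' Runs the full DLW chain per participant: elimination-rate fits for both
#' isotopes, dilution spaces from the dose records, two-pool CO2 production,
#' and TEE as CO2 production (L/day) times the energy equivalent of CO2.
#'
#' @param doses Tibble with `participant_id`, `weight_kg`, `dose_2h2o_g`,
#'   `dose_h218o_g`, `dose_enr_2h`, `dose_enr_18o` (dose enrichments in the
#'   same unit as the urine enrichments).
#' @param urines As in [fit_elimination()].
#' @param food_quotient Diet food quotient; default 0.86 (mixed diet).
#' @param constants [dlw_constants()].
#' @return A tibble of class `dlw_result`, one row per participant:
#'   `k_d`, `k_o` (per day), `n_d`, `n_o` (mol), `dilution_space_ratio`,
#'   `rco2_mol_day`, `rco2_l_day`, `food_quotient`, `energy_equiv_kj_l`,
#'   `tee_kj`, `dsr_qc` (`"ok"` or `"flag"` against the configured
#'   dilution-space-ratio band).
#' @export
dlw_tee <- function(doses, urines, food_quotient = 0.86,
                    constants = dlw_constants()) {
  required <- c("participant_id", "weight_kg", "dose_2h2o_g", "dose_h218o_g",
                "dose_enr_2h", "dose_enr_18o")
  missing <- setdiff(required, names(doses))
  if (length(missing)) {
    abort(paste0("`doses` is missing column(s): ", toString(missing)))
  }

  fits <- fit_elimination(urines)
  wide <- as_tibble(fits) %>%
    tidyr::pivot_wider(
      id_cols = "participant_id",
      names_from = "isotope",
      values_from = c("k", "zero_time_excess", "r_squared", "n_points")
    ) %>%
    rename(
      k_d = "k_2H", k_o = "k_18O",
      e0_d = "zero_time_excess_2H", e0_o = "zero_time_excess_18O"
    )

  res <- doses %>%
    inner_join(wide, by = "participant_id") %>%
    mutate(
      n_d = dilution_space(.data$dose_2h2o_g, .data$dose_enr_2h,
                           .data$e0_d, constants$molar_mass_2h2o),
      n_o = dilution_space(.data$dose_h218o_g, .data$dose_enr_18o,
                           .data$e0_o, constants$molar_mass_h218o),
      dilution_space_ratio = .data$n_d / .data$n_o,
      rco2_mol_day = co2_production(.data$n_d, .data$n_o, .data$k_d,
                                    .data$k_o, constants),
      rco2_l_day = .data$rco2_mol_day * constants$molar_volume_l,
      food_quotient = food_quotient,
      energy_equiv_kj_l = energy_equivalent(food_quotient, constants),
      tee_kj = .data$rco2_l_day * .data$energy_equiv_kj_l,
      dsr_qc = ifelse(
        .data$dilution_space_ratio >= constants$dsr_qc[1] &
          .data$dilution_space_ratio <= constants$dsr_qc[2],
        "ok", "flag"
      )
    ) %>%
    select("participant_id", "weight_kg", "k_d", "k_o", "n_d", "n_o",
           "dilution_space_ratio", "rco2_mol_day", "rco2_l_day",
           "food_quotient", "energy_equiv_kj_l", "tee_kj", "dsr_qc",
           dplyr::starts_with("r_squared"))
  structure(res, class = c("dlw_result", class(res)))
}
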