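#' Configuration for the synthetic validation-cohort generator
#'
#' Defines the study conditions the generator emulates: a cohort of
#' pregnant women with TEE measured by doubly labelled water in a subset,
#' three matched recall days reported through two self-report methods
#' (web and telephone), habitual energy intake tracking TEE with a small
#' level-dependent bias, day-to-day intake variation, correlated
#' between-method reporting errors, guideline food-group intakes with
#' zero-inflated distributions for episodically eaten groups, and
#' two-isotope exponential washout with multiplicative measurement noise.
#'
#' Default calibration pins the marginal distributions to published
#' cohort-level statistics for this population: TEE 10,252 (SD 1197) kJ/day,
#' weight 67.1 (SD 7.6) kg, a mean energy-reporting bias of -2.3% of TEE
#' with a positive bias-on-level slope (lower intakes under-reported,
#' higher over-reported), and food-group means/SDs matching telephone-recall
#' intakes (e.g. fruit & vegetables 426 (149) g/day, fish 33.8 (47.2) g/day).
#' Groups whose SD exceeds the mean (fish, nuts, sweetened beverages,
#' juice) are zero-inflated lognormal; fruit & vegetables is truncated
#' normal.
#'
#' @param n_participants Cohort size (default 52).
#' @param n_dlw Size of the DLW subsample (first `n_dlw` participants).
#' @param n_days Recall days per participant.
#' @param two_day_fraction Fraction of (non-DLW) participants with only two
#'   recall days.
#' @param tee_mean_kj,tee_sd_kj TEE distribution (kJ/day).
#' @param weight_mean_kg,weight_sd_kg Body-weight distribution.
#' @param intake_bias Mean relative bias of habitual intake vs TEE
#'   (-0.023 = habitual intake 2.3% below TEE on average).
#' @param intake_bias_slope Slope of the relative bias on relative TEE
#'   level; positive values make low intakes under-reported and high
#'   intakes over-reported (proportional bias).
#' @param day_cv Within-person day-to-day CV of energy intake.
#' @param method_error_sd SD of the multiplicative per-day reporting error,
#'   shared default for both methods.
#' @param shared_error_cor Correlation between the two methods' reporting
#'   errors on the same day (both are self-report and share common errors).
#' @param energy_epct Named vector of macronutrient E% targets for the
#'   bulk diet (protein, fat, carbohydrate, and the fat subclasses pufa,
#'   mufa, sfa; sucrose as E% of total).
#' @param fibre_g_mj,wholegrain_g_10mj Density targets of the bulk diet.
#' @param food_groups Tibble of per-group distribution settings: `group`,
#'   `mean_g`, `sd_g` (participant-mean scale), `zero_prob`
#'   (never-consumers), `day_zero_prob` (episodic non-consumption days),
#'   `day_cv` and `family` (`"truncnorm"` or `"lognormal"`).
#' @param body_water_fraction Total body water as a fraction of weight.
#' @param dsr_mean,dsr_sd Distribution of the deuterium/oxygen-18
#'   dilution-space ratio.
#' @param k_d_mean,k_d_sd Distribution of the deuterium elimination rate
#'   (per day); the oxygen-18 rate is solved from each participant's TEE.
#' @param dose_2h2o_g_per_kg,dose_h218o_g_per_kg Dosing rules (g per kg).
#' @param dose_enr_2h,dose_enr_18o Dose-water enrichments, in the same unit
#'   as the generated urine excess enrichments (ppm excess).
#' @param enrichment_noise_cv Multiplicative CV of the urine enrichment
#'   measurements (0 = noise-free).
#' @param urine_days,baseline_days Sampling schedule (days since dose).
#' @param food_quotient Diet food quotient used to link TEE and CO2.
#' @param seed Default seed used by [generate_cohort()] when none is given.
#' @return A validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_participants = 52, n_dlw = 24, n_days = 3,
                          two_day_fraction = 0.077,
                          tee_mean_kj = 10252, tee_sd_kj = 1197,
                          weight_mean_kg = 67.1, weight_sd_kg = 7.6,
                          intake_bias = -0.023, intake_bias_slope = 0.3,
                          day_cv = 0.23,
                          method_error_sd = 0.18, shared_error_cor = 0.25,
                          energy_epct = c(protein = 15.0, fat = 41.5,
                                          carbohydrate = 41.3, sucrose = 7.6,
                                          pufa = 5.9, mufa = 15.3,
                                          sfa = 16.7),
                          fibre_g_mj = 2.54, wholegrain_g_10mj = 42.6,
                          food_groups = default_food_group_params(),
                          body_water_fraction = 0.50,
                          dsr_mean = 1.035, dsr_sd = 0.010,
                          k_d_mean = 0.09, k_d_sd = 0.006,
                          dose_2h2o_g_per_kg = 0.08,
                          dose_h218o_g_per_kg = 0.15,
                          dose_enr_2h = 999000, dose_enr_18o = 100000,
                          enrichment_noise_cv = 0.015,
                          urine_days = c(1, 5, 8, 12, 15),
                          baseline_days = c(-2, -1),
                          food_quotient = 0.86,
                          seed = 1L) {
  cfg <- structure(as.list(environment()), class = "cohort_config")
  validate_cohort_config(cfg)
  cfg
}

#' Default food-group distribution parameters
#'
#' Participant-mean scale distributions per guideline group, calibrated to
#' cohort means/SDs observed in pregnant Swedish women; episodically
#' consumed groups carry day-level zero-inflation.
#'
#' @return A tibble used by [cohort_config()].
#' @export
default_food_group_params <- function() {
  tibble(
    group = FOOD_GROUPS,
    mean_g = c(426, 33.8, 9, 39, 28, 70, 107, 78, 95),
    sd_g = c(149, 47.2, 11, 44, 33, 46, 177, 159, 108),
    zero_prob = c(0, 0.10, 0.15, 0.05, 0.05, 0, 0.25, 0.40, 0.20),
    day_zero_prob = c(0, 0.6, 0.5, 0.4, 0.4, 0.1, 0.5, 0.5, 0.5),
    day_cv = c(0.25, 0.5, 0.5, 0.5, 0.5, 0.4, 0.5, 0.5, 0.5),
    family = c("truncnorm", rep("lognormal", 8))
  )
}

validate_cohort_config <- function(cfg) {
  with(cfg, {
    stopifnot(
      n_participants >= 1, n_dlw >= 0, n_dlw <= n_participants,
      n_days >= 1, two_day_fraction >= 0, two_day_fraction <= 1,
      tee_sd_kj >= 0, weight_sd_kg >= 0, day_cv >= 0,
      method_error_sd >= 0,
      shared_error_cor >= -1, shared_error_cor <= 1,
      body_water_fraction > 0, body_water_fraction < 1,
      dsr_sd >= 0, k_d_sd >= 0, enrichment_noise_cv >= 0,
      food_quotient >= 0.7, food_quotient <= 1.0,
      dose_2h2o_g_per_kg > 0, dose_h218o_g_per_kg > 0,
      dose_enr_2h > 0, dose_enr_18o > 0
    )
    if (any(food_groups$zero_prob < 0 | food_groups$zero_prob > 1) ||
        any(food_groups$day_zero_prob < 0 | food_groups$day_zero_prob >= 1)) {
      abort("Food-group zero-probabilities must lie in [0, 1).")
    }
    if (any(food_groups$sd_g < 0)) abort("Food-group SDs must be >= 0.")
    if (!setequal(food_groups$group, FOOD_GROUPS)) {
      abort("`food_groups` must cover exactly the nine guideline groups.")
    }
  })
  invisible(cfg)
}

# truncated-normal sampling via inverse CDF (keeps the stream deterministic)
rtruncnorm_ <- function(n, mean, sd, lower = -Inf) {
  if (all(sd == 0)) return(rep(mean, length.out = n))
  p_lo <- stats::pnorm((lower - mean) / sd)
  mean + sd * qnorm(p_lo + runif(n) * (1 - p_lo))
}

# lognormal with a given arithmetic mean and sd
rlnorm_ms <- function(n, mean, sd) {
  if (all(mean <= 0)) return(rep(0, n))
  s2 <- log(1 + (sd / mean)^2)
  rlnorm(n, meanlog = log(mean) - s2 / 2, sdlog = sqrt(s2))
}

# multiplicative noise with mean 1 and the given CV (vectorised over cv)
rnoise_mult <- function(n, cv) {
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Synthetic food-composition and food-group tables
#'
#' Builds the composition table used by [generate_cohort()]: three food
#' codes per guideline group (a base nutrient profile scaled to three
#' energy densities) plus three group-free "bulk diet" codes whose
#' macronutrient shares reproduce the configured E% targets and fibre /
#' wholegrain densities. Entirely synthetic; no proprietary database values.
#'
#' @param cfg A [cohort_config()].
#' @return A list with `composition` and `foodgroups` tibbles.
#' @export
synthetic_food_tables <- function(cfg = cohort_config()) {
  profiles <- tibble(
    group = FOOD_GROUPS,
    energy_kj = c(180, 550, 2500, 800, 1100, 1800, 180, 5, 190),
    protein_g = c(1.5, 20, 20, 21, 14, 5, 0, 0, 0.5),
    fat_g = c(0.3, 5, 55, 12, 23, 20, 0, 0, 0.1),
    carbohydrate_g = c(8, 0, 10, 0, 1, 55, 10.5, 0.3, 10),
    sucrose_g = c(3, 0, 1, 0, 0, 30, 10.5, 0, 9),
    fibre_g = c(2.5, 0, 7, 0, 0, 1.5, 0, 0, 0.2),
    wholegrain_g = c(0, 0, 0, 0, 0, 2, 0, 0, 0),
    pufa_g = c(0.1, 1.5, 15, 0.8, 2, 2, 0, 0, 0),
    mufa_g = c(0.1, 2, 30, 5, 10, 7, 0, 0, 0),
    sfa_g = c(0.1, 1, 8, 5, 9, 10, 0, 0, 0.05)
  )
  scales <- c(0.8, 1.0, 1.2)
  group_foods <- tidyr::expand_grid(profiles, scale = scales) %>%
    mutate(
      food_code = paste0(toupper(substr(.data$group, 1, 3)), "_",
                         .data$group, "_", match(.data$scale, scales)),
      across(all_of(NUTRIENT_COLS), ~ .x * .data$scale)
    )

  # bulk-diet codes: exact E% targets at three energy densities
  ep <- cfg$energy_epct
  fct <- energy_factors()
  bulk <- purrr::map_dfr(seq_along(scales), function(i) {
    e <- c(600, 800, 1000)[i] # kJ per 100 g
    fat_g <- ep[["fat"]] / 100 * e / fct$fat
    fat_split <- c(ep[["pufa"]], ep[["mufa"]], ep[["sfa"]])
    fat_split <- fat_split / sum(fat_split) * fat_g
    tibble(
      group = NA_character_, scale = NA_real_,
      food_code = paste0("BULK_", i),
      energy_kj = e,
      protein_g = ep[["protein"]] / 100 * e / fct$protein,
      fat_g = fat_g,
      carbohydrate_g = ep[["carbohydrate"]] / 100 * e / fct$carbohydrate,
      sucrose_g = max(ep[["sucrose"]] - 1.5, 0) / 100 * e / fct$sucrose,
      fibre_g = cfg$fibre_g_mj * e / 1000,
      wholegrain_g = cfg$wholegrain_g_10mj * e / 10000,
      pufa_g = fat_split[1], mufa_g = fat_split[2], sfa_g = fat_split[3]
    )
  })

  composition <- bind_rows(group_foods, bulk) %>%
    select("food_code", all_of(NUTRIENT_COLS))
  foodgroups <- group_foods %>%
    select("food_code", "group")
  list(composition = composition, foodgroups = foodgroups)
}

#' Generate a complete synthetic validation cohort
#'
#' Produces every table the pipeline consumes -- item-level recalls for the
#' two assessment methods, the food-composition and food-group tables, DLW
#' dose records and urine enrichment series for the DLW subsample -- plus a
#' `ground_truth` sidecar holding the per-participant quantities the data
#' were generated from (TEE, habitual intake, food-group means, isotope
#' kinetics). Ground truth is never consumed by any pipeline stage; it
#' exists so that tests can measure recovery.
#'
#' Generation model, per participant i and day d:
#' * TEE_i ~ Normal(mean, SD); habitual intake
#'   `H_i = TEE_i * (1 + bias + slope * (TEE_i - mean)/mean)`;
#' * true daily energy `E_id = H_i * (1 + delta_id)`, delta ~ Normal(0, CV);
#' * each method's reported day scales all item amounts by `(1 + e_mid)`
#'   with `(e_web, e_tel)` jointly normal, shared correlation rho;
#' * food-group grams drawn per group (participant mean, then day-level
#'   zero-inflation and noise) and split over that group's three food
#'   codes; "bulk diet" codes fill the remaining energy to `E_id`;
#' * urine excess enrichments follow `E0 * exp(-k t)` for both isotopes at
#'   the scheduled days with multiplicative noise; two pre-dose baselines
#'   at zero excess. The oxygen-18 rate is solved so that the two-pool CO2
#'   equation returns exactly the participant's TEE.
#'
#' @param cfg A [cohort_config()].
#' @param seed Integer seed; defaults to `cfg$seed`. The same seed yields
#'   identical output.
#' @param constants [dlw_constants()] shared with the analysis chain.
#' @return A list of class `synthetic_cohort` with elements `recalls`,
#'   `composition`, `foodgroups`, `doses`, `urines`, `ground_truth`, and
#'   the `config` used.
#' @examples
#' cohort <- generate_cohort(cohort_config(n_participants = 4, n_dlw = 2))
#' names(cohort)
#' @export
generate_cohort <- function(cfg = cohort_config(), seed = cfg$seed,
                            constants = dlw_constants()) {
  validate_cohort_config(cfg)
  set.seed(seed)
  n <- cfg$n_participants
  ids <- sprintf("P%03d", seq_len(n))
  is_dlw <- seq_len(n) <= cfg$n_dlw

  weight <- rtruncnorm_(n, cfg$weight_mean_kg, cfg$weight_sd_kg, lower = 45)
  tee <- rtruncnorm_(n, cfg$tee_mean_kj, cfg$tee_sd_kj, lower = 6000)
  rel <- (tee - cfg$tee_mean_kj) / cfg$tee_mean_kj
  habitual <- tee * (1 + cfg$intake_bias + cfg$intake_bias_slope * rel)

  # participants with only two recall days (never in the DLW subsample)
  n_two <- round(cfg$two_day_fraction * n)
  two_day <- rep(FALSE, n)
  eligible <- which(!is_dlw)
  if (n_two > 0 && length(eligible)) {
    pick <- sample.int(length(eligible), min(n_two, length(eligible)))
    two_day[eligible[pick]] <- TRUE
  }
  n_days_i <- ifelse(two_day, pmax(cfg$n_days - 1, 1), cfg$n_days)

  # participant-level food-group means
  fg <- cfg$food_groups
  group_means <- purrr::pmap(fg, function(group, mean_g, sd_g, zero_prob,
                                          day_zero_prob, day_cv, family) {
    never <- runif(n) < zero_prob
    m <- if (family == "truncnorm") {
      rtruncnorm_(n, mean_g, sd_g, lower = 0)
    } else {
      mean_pos <- mean_g / (1 - zero_prob)
      rlnorm_ms(n, mean_pos, sd_g)
    }
    ifelse(never, 0, m)
  })
  names(group_means) <- fg$group
  group_means <- as_tibble(group_means)

  tables <- synthetic_food_tables(cfg)
  composition <- tables$composition
  foodgroups <- tables$foodgroups
  energy_per_g <- setNames(composition$energy_kj / 100, composition$food_code)

  # per participant-day scaffold
  days <- tidyr::expand_grid(idx = seq_len(n), day_index = seq_len(cfg$n_days)) %>%
    filter(.data$day_index <= n_days_i[.data$idx]) %>%
    mutate(
      participant_id = ids[.data$idx],
      is_weekend = .data$day_index == cfg$n_days,
      delta = rtruncnorm_(n(), 0, cfg$day_cv, lower = -0.8),
      energy_target = habitual[.data$idx] * (1 + .data$delta)
    )
  # correlated reporting errors, one pair per participant-day
  z0 <- rnorm(nrow(days))
  zw <- rnorm(nrow(days))
  zt <- rnorm(nrow(days))
  rho <- cfg$shared_error_cor
  days$e_web <- pmax(cfg$method_error_sd * (sqrt(rho) * z0 + sqrt(1 - rho) * zw), -0.8)
  days$e_tel <- pmax(cfg$method_error_sd * (sqrt(rho) * z0 + sqrt(1 - rho) * zt), -0.8)

  # day-level food-group grams
  day_groups <- tidyr::expand_grid(
    days %>% select("idx", "participant_id", "day_index"),
    fg %>% select("group", "day_zero_prob", day_cv_g = "day_cv")
  ) %>%
    mutate(m = purrr::map2_dbl(.data$idx, .data$group,
                               ~ group_means[[.y]][.x])) %>%
    mutate(
      eaten = rbinom(n(), 1, 1 - .data$day_zero_prob),
      grams = .data$m / (1 - .data$day_zero_prob) * .data$eaten *
        rnoise_mult(n(), .data$day_cv_g)
    )

  # split group grams over the group's three codes
  code_map <- foodgroups %>%
    group_by(.data$group) %>%
    summarise(codes = list(.data$food_code), .groups = "drop")
  day_items <- day_groups %>%
    filter(.data$grams > 0) %>%
    left_join(code_map, by = "group") %>%
    mutate(shares = purrr::map(.data$codes, function(codes) {
      w <- runif(length(codes))
      w / sum(w)
    })) %>%
    tidyr::unnest(c("codes", "shares")) %>%
    mutate(food_code = .data$codes, amount_g = .data$grams * .data$shares) %>%
    select("idx", "participant_id", "day_index", "food_code", "amount_g")

  # bulk-diet codes fill the energy gap to the day's target
  group_energy <- day_items %>%
    mutate(kj = .data$amount_g * energy_per_g[.data$food_code]) %>%
    group_by(.data$idx, .data$participant_id, .data$day_index) %>%
    summarise(group_kj = sum(.data$kj), .groups = "drop")
  bulk_codes <- grep("^BULK_", composition$food_code, value = TRUE)
  bulk_items <- days %>%
    left_join(group_energy, by = c("idx", "participant_id", "day_index")) %>%
    mutate(
      group_kj = tidyr::replace_na(.data$group_kj, 0),
      remaining_kj = pmax(.data$energy_target - .data$group_kj, 0)
    ) %>%
    select("idx", "participant_id", "day_index", "remaining_kj") %>%
    tidyr::expand_grid(food_code = bulk_codes) %>%
    group_by(.data$idx, .data$day_index) %>%
    mutate(share = {
      w <- runif(n())
      w / sum(w)
    }) %>%
    ungroup() %>%
    mutate(amount_g = .data$remaining_kj * .data$share /
             energy_per_g[.data$food_code]) %>%
    filter(.data$amount_g > 0) %>%
    select("idx", "participant_id", "day_index", "food_code", "amount_g")

  base_items <- bind_rows(day_items, bulk_items)

  # one reported copy per method, all amounts scaled by the day's error
  err <- days %>%
    select("idx", "day_index", "is_weekend", "e_web", "e_tel") %>%
    tidyr::pivot_longer(c("e_web", "e_tel"), names_to = "method",
                        values_to = "e") %>%
    mutate(method = ifelse(.data$method == "e_web",
                           "web_recall", "telephone_recall"))
  recalls <- base_items %>%
    inner_join(err, by = c("idx", "day_index"),
               relationship = "many-to-many") %>%
    mutate(amount_g = .data$amount_g * (1 + .data$e)) %>%
    select("participant_id", "method", "day_index", "is_weekend",
           "food_code", "amount_g") %>%
    arrange(.data$participant_id, .data$method, .data$day_index,
            .data$food_code)

  # ---- DLW subsample -------------------------------------------------------
  dlw_idx <- which(is_dlw)
  doses <- urines <- NULL
  kin <- tibble(
    participant_id = ids, k_d = NA_real_, k_o = NA_real_,
    n_d = NA_real_, n_o = NA_real_, dilution_space_ratio = NA_real_
  )
  if (length(dlw_idx)) {
    w <- weight[dlw_idx]
    n_o <- w * cfg$body_water_fraction * 1000 / 18.015
    dsr <- rtruncnorm_(length(dlw_idx), cfg$dsr_mean, cfg$dsr_sd, lower = 0.95)
    n_d <- dsr * n_o
    k_d <- rtruncnorm_(length(dlw_idx), cfg$k_d_mean, cfg$k_d_sd, lower = 0.06)

    ee <- energy_equivalent(cfg$food_quotient, constants)
    rco2_mol <- tee[dlw_idx] / ee / constants$molar_volume_l
    n_pool <- (n_d / constants$dsr_norm + n_o) / 2
    scale <- 1 / constants$pool_divisor -
      constants$frac_water * constants$breath_frac
    delta <- rco2_mol / (n_pool * scale)
    k_o <- (delta + constants$frac_d * k_d) / constants$frac_o

    dose_2h <- cfg$dose_2h2o_g_per_kg * w
    dose_18o <- cfg$dose_h218o_g_per_kg * w
    e0_d <- (dose_2h / constants$molar_mass_2h2o) * cfg$dose_enr_2h / n_d
    e0_o <- (dose_18o / constants$molar_mass_h218o) * cfg$dose_enr_18o / n_o

    doses <- tibble(
      participant_id = ids[dlw_idx], weight_kg = w,
      dose_2h2o_g = dose_2h, dose_h218o_g = dose_18o,
      dose_enr_2h = cfg$dose_enr_2h, dose_enr_18o = cfg$dose_enr_18o
    )
    sched <- tidyr::expand_grid(
      j = seq_along(dlw_idx),
      time_days = c(cfg$baseline_days, cfg$urine_days)
    ) %>%
      mutate(is_baseline = .data$time_days %in% cfg$baseline_days)
    urines <- sched %>%
      mutate(
        participant_id = ids[dlw_idx][.data$j],
        enr_2h = ifelse(
          .data$is_baseline, 0,
          e0_d[.data$j] * exp(-k_d[.data$j] * .data$time_days) *
            rnoise_mult(n(), cfg$enrichment_noise_cv)
        ),
        enr_18o = ifelse(
          .data$is_baseline, 0,
          e0_o[.data$j] * exp(-k_o[.data$j] * .data$time_days) *
            rnoise_mult(n(), cfg$enrichment_noise_cv)
        )
      ) %>%
      select("participant_id", "time_days", "enr_2h", "enr_18o",
             "is_baseline")

    kin$k_d[dlw_idx] <- k_d
    kin$k_o[dlw_idx] <- k_o
    kin$n_d[dlw_idx] <- n_d
    kin$n_o[dlw_idx] <- n_o
    kin$dilution_space_ratio[dlw_idx] <- dsr
  }

  ground_truth <- tibble(
    participant_id = ids, weight_kg = weight, tee_kj = tee,
    habitual_intake_kj = habitual, n_days = n_days_i, in_dlw = is_dlw
  ) %>%
    bind_cols(setNames(group_means, paste0("true_", fg$group, "_g"))) %>%
    left_join(kin, by = "participant_id")

  structure(
    list(
      recalls = recalls, composition = composition, foodgroups = foodgroups,
      doses = doses, urines = urines, ground_truth = ground_truth,
      config = cfg, seed = seed
    ),
    class = "synthetic_cohort"
  )
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("Synthetic validation cohort\n")
  cat("  participants:", x$config$n_participants,
      "(DLW subsample:", x$config$n_dlw, ")\n")
  cat("  recall rows:", nrow(x$recalls), "| food codes:",
      nrow(x$composition), "| seed:", x$seed, "\n")
  invisible(x)
}

#' Monte-Carlo calibration check of the generator
#'
#' Generates `replicates` independent cohorts, runs each through the
#' dietary aggregation, and summarises the agreement statistics the
#' generator is supposed to induce: the energy-intake-vs-TEE mean
#' difference, limits of agreement, the sign of the difference-on-average
#' slope (proportional bias), and the web-vs-telephone energy correlation.
#'
#' @param cfg A [cohort_config()]; the DLW comparison uses the DLW
#'   subsample, so set `n_dlw` accordingly.
#' @param replicates Number of simulated cohorts (>= 50 recommended).
#' @param seed Seed for the replicate stream.
#' @return A list with `replicates` (per-replicate tibble: `mean_diff`,
#'   `loa_half_width`, `slope`, `r_ei_tee`, `r_web_tel`) and `summary`
#'   (means, medians and central 95% interval of the mean difference).
#' @export
calibration_check <- function(cfg = cohort_config(), replicates = 200,
                              seed = 1L) {
  stopifnot(replicates >= 1)
  reps <- purrr::map_dfr(seq_len(replicates), function(r) {
    cohort <- generate_cohort(cfg, seed = seed + r)
    daily <- aggregate_days(cohort$recalls, cohort$composition,
                            cohort$foodgroups)
    pm <- participant_means(daily)
    energy <- pm %>%
      select("participant_id", "method", "energy_kj") %>%
      tidyr::pivot_wider(names_from = "method", values_from = "energy_kj") %>%
      inner_join(select(cohort$ground_truth, "participant_id", "tee_kj",
                        "in_dlw"),
                 by = "participant_id")
    dlw_part <- filter(energy, .data$in_dlw)
    ba <- bland_altman(dlw_part, .data$web_recall, .data$tee_kj)
    tibble(
      mean_diff = ba$stats$mean_diff,
      loa_half_width = ba$stats$loa_half_width,
      slope = ba$stats$slope,
      r_ei_tee = cor(dlw_part$web_recall, dlw_part$tee_kj),
      r_web_tel = cor(energy$web_recall, energy$telephone_recall)
    )
  })
  configured_bias_kj <- cfg$intake_bias * cfg$tee_mean_kj
  list(
    replicates = reps,
    summary = tibble(
      configured_bias_kj = configured_bias_kj,
      mean_diff_mean = mean(reps$mean_diff),
      mean_diff_lo = quantile(reps$mean_diff, 0.025, names = FALSE),
      mean_diff_hi = quantile(reps$mean_diff, 0.975, names = FALSE),
      median_slope = median(reps$slope),
      prop_slope_positive = mean(reps$slope > 0),
      median_r_ei_tee = median(reps$r_ei_tee),
      median_r_web_tel = median(reps$r_web_tel)
    )
  )
}
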