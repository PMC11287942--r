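#' Aggregate consumed items into daily nutrient and food-group intakes
#'
#' Turns an item-level recall table (one row per consumed food) into one row
#' per participant-day-method carrying total energy, nutrient masses,
#' energy percentages, density-normalised fibre and wholegrain, grams per
#' guideline food group, and an energy-plausibility flag.
#'
#' Every `food_code` in `recalls` must resolve in `composition`; an
#' unresolvable code is a hard error naming the code. A food may map to any
#' number of groups in `foodgroups` (including none); groups not eaten on a
#' day are reported as 0 g, not missing. Days listed in `days` but absent
#' from `recalls` (no items reported) become valid all-zero days and are
#' flagged `"low"`. Missing nutrient values in the composition table are
#' treated as zero with a warning.
#'
#' @param recalls Tibble with columns `participant_id`, `method`,
#'   `day_index`, `is_weekend`, `food_code`, `amount_g` (one row per item;
#'   `amount_g` >= 0).
#' @param composition Food-composition tibble: `food_code` plus the per-100 g
#'   nutrient columns `energy_kj`, `protein_g`, `fat_g`, `carbohydrate_g`,
#'   `sucrose_g`, `fibre_g`, `wholegrain_g`, `pufa_g`, `mufa_g`, `sfa_g`.
#' @param foodgroups Tibble `food_code`, `group`; `group` restricted to the
#'   nine guideline groups (see [food_groups()]).
#' @param factors [energy_factors()] used for E% columns.
#' @param plausibility [plausibility_config()] for the energy screen.
#' @param days Optional tibble (`participant_id`, `method`, `day_index`,
#'   `is_weekend`) enumerating the days that should appear in the output
#'   even when no items were reported for them.
#'
#' @return A tibble, one row per (participant, method, day), with columns
#'   `energy_kj`, `<nutrient>_g`, `<nutrient>_epct`, `fibre_g_mj`,
#'   `wholegrain_g_10mj`, `<group>_g` for the nine groups, and `flag`.
#' @seealso [participant_means()], [cohort_summary()]
#' @export
aggregate_days <- function(recalls, composition, foodgroups,
                           factors = energy_factors(),
                           plausibility = plausibility_config(),
                           days = NULL) {
  check_recalls(recalls)
  composition <- check_composition(composition)
  foodgroups <- check_foodgroups(foodgroups)

  unknown <- setdiff(unique(recalls$food_code), composition$food_code)
  if (length(unknown)) {
    abort(paste0(
      "Food code(s) not found in the composition table: ",
      toString(head(unknown, 10))
    ))
  }

  items <- recalls %>%
    left_join(composition, by = "food_code") %>%
    mutate(across(all_of(NUTRIENT_COLS), ~ .x * .data$amount_g / 100))

  key <- c("participant_id", "method", "day_index", "is_weekend")
  daily <- items %>%
    group_by(across(all_of(key))) %>%
    summarise(across(all_of(NUTRIENT_COLS), sum), .groups = "drop")

  # grams per guideline group; a food may contribute to several groups
  group_totals <- items %>%
    inner_join(foodgroups, by = "food_code", relationship = "many-to-many") %>%
    group_by(across(all_of(c(key, "group")))) %>%
    summarise(grams = sum(.data$amount_g), .groups = "drop") %>%
    tidyr::pivot_wider(
      names_from = "group", values_from = "grams",
      names_glue = "{group}_g", values_fill = 0
    )

  daily <- daily %>% left_join(group_totals, by = key)
  for (g in paste0(FOOD_GROUPS, "_g")) {
    if (!g %in% names(daily)) daily[[g]] <- 0
    daily[[g]][is.na(daily[[g]])] <- 0
  }

  if (!is.null(days)) {
    days <- as_tibble(days)[key]
    daily <- days %>% left_join(daily, by = key)
    zero_cols <- setdiff(names(daily)[vapply(daily, is.numeric, logical(1))],
                         "day_index")
    daily <- daily %>%
      mutate(across(all_of(zero_cols), ~ tidyr::replace_na(.x, 0)))
  }

  daily %>%
    mutate(
      protein_epct = energy_percent(.data$protein_g, factors$protein, .data$energy_kj),
      fat_epct = energy_percent(.data$fat_g, factors$fat, .data$energy_kj),
      carbohydrate_epct = energy_percent(.data$carbohydrate_g, factors$carbohydrate, .data$energy_kj),
      sucrose_epct = energy_percent(.data$sucrose_g, factors$sucrose, .data$energy_kj),
      pufa_epct = energy_percent(.data$pufa_g, factors$fatty_acid, .data$energy_kj),
      mufa_epct = energy_percent(.data$mufa_g, factors$fatty_acid, .data$energy_kj),
      sfa_epct = energy_percent(.data$sfa_g, factors$fatty_acid, .data$energy_kj),
      fibre_g_mj = ifelse(.data$energy_kj > 0, .data$fibre_g / (.data$energy_kj / 1000), NA_real_),
      wholegrain_g_10mj = ifelse(.data$energy_kj > 0, .data$wholegrain_g / (.data$energy_kj / 10000), NA_real_),
      flag = plausibility_flag(.data$energy_kj, plausibility)
    ) %>%
    select(all_of(key), "energy_kj", all_of(setdiff(NUTRIENT_COLS, "energy_kj")),
           dplyr::ends_with("_epct"), "fibre_g_mj", "wholegrain_g_10mj",
           all_of(paste0(FOOD_GROUPS, "_g")), "flag") %>%
    arrange(.data$participant_id, .data$method, .data$day_index)
}

#' Aggregate a single recall day
#'
#' Convenience wrapper around [aggregate_days()] for one participant-day.
#' An empty item list is a valid day with all-zero intake (flagged `"low"`).
#'
#' @param items Tibble `food_code`, `amount_g` (possibly zero rows).
#' @param composition,foodgroups,factors,plausibility As in
#'   [aggregate_days()].
#' @param participant_id,method,day_index,is_weekend Identifiers attached to
#'   the returned row.
#' @return A one-row daily-intake tibble.
#' @export
aggregate_day <- function(items, composition, foodgroups,
                          factors = energy_factors(),
                          plausibility = plausibility_config(),
                          participant_id = "p1", method = "web_recall",
                          day_index = 1L, is_weekend = FALSE) {
  items <- as_tibble(items)
  recalls <- tibble(
    participant_id = participant_id, method = method,
    day_index = day_index, is_weekend = is_weekend,
    food_code = items$food_code, amount_g = items$amount_g
  )
  days <- tibble(
    participant_id = participant_id, method = method,
    day_index = day_index, is_weekend = is_weekend
  )
  aggregate_days(recalls, composition, foodgroups, factors, plausibility,
                 days = days)
}

#' Per-participant mean intakes over available recall days
#'
#' Averages every daily-intake field over a participant's available days
#' (per method) and derives weekly red-plus-processed-meat intake as
#' 7 x the daily mean. Days flagged by the energy screen are retained by
#' default, mirroring protocols where flagged days are manually checked and
#' kept when plausible.
#'
#' @param daily Output of [aggregate_days()].
#' @param exclude_flagged If `TRUE`, drop days with flag `"low"`/`"high"`
#'   before averaging (a participant loses all days only if every day is
#'   flagged, in which case they are dropped with a warning).
#' @return A tibble, one row per participant x method, with `n_days`, the
#'   mean of every numeric daily field, and `red_processed_meat_weekly`
#'   (g/week).
#' @export
participant_means <- function(daily, exclude_flagged = FALSE) {
  stopifnot(is.data.frame(daily), nrow(daily) >= 1)
  if (exclude_flagged) {
    kept <- daily %>% filter(.data$flag == "ok")
    dropped <- dplyr::anti_join(
      distinct(daily, .data$participant_id, .data$method),
      distinct(kept, .data$participant_id, .data$method),
      by = c("participant_id", "method")
    )
    if (nrow(dropped)) {
      warn(paste0(nrow(dropped), " participant-method series lost all days ",
                  "to the plausibility screen and were dropped."))
    }
    daily <- kept
    if (!nrow(daily)) abort("No days left after excluding flagged days.")
  }
  num_cols <- setdiff(
    names(daily)[vapply(daily, is.numeric, logical(1))],
    c("day_index")
  )
  daily %>%
    group_by(.data$participant_id, .data$method) %>%
    summarise(
      n_days = n(),
      across(all_of(num_cols), ~ mean(.x)),
      .groups = "drop"
    ) %>%
    mutate(
      red_processed_meat_weekly = 7 * (.data$red_meat_g + .data$processed_meat_g)
    )
}

#' Cohort-level mean (SD) summary per variable and method
#'
#' @param participants Output of [participant_means()] (>= 2 participants).
#' @param variables Character vector of columns to summarise; defaults to
#'   every numeric intake column.
#' @return A long tibble: `variable`, `method`, `n`, `mean`, `sd` (sample
#'   SD, n - 1 denominator).
#' @export
cohort_summary <- function(participants, variables = NULL) {
  stopifnot(is.data.frame(participants))
  if (n_distinct(participants$participant_id) < 2) {
    abort("`cohort_summary()` needs at least 2 participants.")
  }
  if (is.null(variables)) {
    variables <- setdiff(
      names(participants)[vapply(participants, is.numeric, logical(1))],
      "n_days"
    )
  }
  participants %>%
    tidyr::pivot_longer(all_of(variables), names_to = "variable") %>%
    group_by(.data$variable, .data$method) %>%
    summarise(
      n = sum(!is.na(.data$value)),
      mean = mean(.data$value, na.rm = TRUE),
      sd = sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    )
}

#' The nine guideline food groups
#'
#' @return Character vector of the food-group labels used throughout the
#'   package.
#' @export
food_groups <- function() FOOD_GROUPS

# ---- input checks ----------------------------------------------------------

check_recalls <- function(recalls) {
  required <- c("participant_id", "method", "day_index", "is_weekend",
                "food_code", "amount_g")
  missing <- setdiff(required, names(recalls))
  if (length(missing)) {
    abort(paste0("`recalls` is missing column(s): ", toString(missing)))
  }
  if (any(recalls$amount_g < 0, na.rm = TRUE)) {
    abort("`amount_g` must be non-negative.")
  }
  if (!all(recalls$day_index %in% 1:3)) {
    warn("`day_index` values outside 1-3 found; study-conformant data has 2-3 days.")
  }
  invisible(recalls)
}

check_composition <- function(composition, energy_tolerance = 0.25,
                              factors = energy_factors()) {
  missing <- setdiff(c("food_code", NUTRIENT_COLS), names(composition))
  if (length(missing)) {
    abort(paste0("`composition` is missing column(s): ", toString(missing)))
  }
  composition <- as_tibble(composition)
  if (anyNA(composition[NUTRIENT_COLS])) {
    warn("Missing nutrient values in the composition table treated as 0.")
    composition <- composition %>%
      mutate(across(all_of(NUTRIENT_COLS), ~ tidyr::replace_na(.x, 0)))
  }
  neg <- vapply(composition[NUTRIENT_COLS], function(x) any(x < 0), logical(1))
  if (any(neg)) {
    abort(paste0("Negative composition values in: ",
                 toString(NUTRIENT_COLS[neg])))
  }
  # soft consistency screen: tabulated energy vs macronutrient-derived energy
  macro_kj <- factors$protein * composition$protein_g +
    factors$fat * composition$fat_g +
    factors$carbohydrate * composition$carbohydrate_g
  off <- composition$energy_kj > 0 &
    abs(composition$energy_kj - macro_kj) / composition$energy_kj > energy_tolerance
  if (any(off)) {
    warn(paste0(
      sum(off), " composition row(s) have energy inconsistent with their ",
      "macronutrients beyond ", 100 * energy_tolerance, "% (kept as-is)."
    ))
  }
  composition
}

check_foodgroups <- function(foodgroups) {
  missing <- setdiff(c("food_code", "group"), names(foodgroups))
  if (length(missing)) {
    abort(paste0("`foodgroups` is missing column(s): ", toString(missing)))
  }
  bad <- setdiff(unique(foodgroups$group), FOOD_GROUPS)
  if (length(bad)) {
    abort(paste0("Unknown food group label(s): ", toString(bad)))
  }
  as_tibble(foodgroups)
}
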