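#' Default Swedish Healthy Eating Index component configuration
#'
#' The SHEI scores adherence to Swedish food-based dietary guidelines with
#' nine components, each worth 0-1 point, summed to a 0-9 total. Each
#' component is scored by a continuous piecewise-linear ramp between a
#' `lower_ref` and an `upper_ref` in the component's own unit:
#'
#' * `higher_better`: 0 at or below `lower_ref`, 1 at or above `upper_ref`;
#' * `lower_better`: the mirror image (1 at or below `lower_ref`);
#' * `range_better`: 1 inside `[lower_ref, upper_ref]`, ramping to 0 at
#'   `outer_lower` / `outer_upper`.
#'
#' The shipped cut-offs follow the Swedish guideline targets the index is
#' built around (e.g. 500 g/day fruit and vegetables, at most 500 g/week red
#' and processed meat, at most 10 E% added sugar) but every number is
#' configuration, not code: pass an edited tibble, or load one from YAML
#' with [read_shei_config()], to rescore against different references. The
#' red-meat component uses combined red + processed meat in g/week, and the
#' added-sugar component defaults to sucrose E%; both choices are switchable
#' by editing the `column` field.
#'
#' @return A tibble with columns `component`, `column` (the
#'   participant-intake column scored), `unit`, `direction`, `lower_ref`,
#'   `upper_ref`, `outer_lower`, `outer_upper`.
#' @seealso [shei_score()], [shei_component_score()]
#' @export
shei_config <- function() {
  tibble(
    component = c("fruit_veg", "wholegrain", "fibre", "fish_shellfish",
                  "pufa", "mufa", "sfa", "red_processed_meat", "added_sugar"),
    column = c("fruit_veg_g", "wholegrain_g_10mj", "fibre_g_mj",
               "fish_shellfish_g", "pufa_epct", "mufa_epct", "sfa_epct",
               "red_processed_meat_weekly", "sucrose_epct"),
    unit = c("g/day", "g/10 MJ", "g/MJ", "g/day", "E%", "E%", "E%",
             "g/week", "E%"),
    direction = c("higher_better", "higher_better", "higher_better",
                  "higher_better", "range_better", "range_better",
                  "lower_better", "lower_better", "lower_better"),
    lower_ref = c(0, 0, 2, 0, 5, 10, 10, 500, 10),
    upper_ref = c(500, 75, 3, 35, 10, 20, 17, 700, 20),
    outer_lower = c(NA, NA, NA, NA, 0, 0, NA, NA, NA),
    outer_upper = c(NA, NA, NA, NA, 15, 30, NA, NA, NA)
  )
}

#' Read a SHEI component configuration from YAML
#'
#' The file holds one block per component with fields `component`, `column`,
#' `unit`, `direction`, `lower_ref`, `upper_ref` and (for `range_better`)
#' `outer_lower`, `outer_upper`.
#'
#' @param path Path to a YAML file.
#' @return A config tibble as returned by [shei_config()].
#' @export
read_shei_config <- function(path) {
  blocks <- yaml::read_yaml(path)
  cfg <- purrr::map_dfr(blocks, function(b) {
    as_tibble(modifyList(
      list(outer_lower = NA_real_, outer_upper = NA_real_), b
    ))
  })
  validate_shei_config(cfg)
  cfg
}

validate_shei_config <- function(cfg) {
  required <- c("component", "column", "unit", "direction",
                "lower_ref", "upper_ref")
  missing <- setdiff(required, names(cfg))
  if (length(missing)) {
    abort(paste0("SHEI config is missing field(s): ", toString(missing)))
  }
  if (!all(cfg$direction %in% c("higher_better", "lower_better", "range_better"))) {
    abort("SHEI `direction` must be higher_better, lower_better or range_better.")
  }
  if (any(cfg$lower_ref >= cfg$upper_ref)) {
    abort("SHEI config requires lower_ref < upper_ref for every component.")
  }
  rb <- cfg$direction == "range_better"
  if (any(rb & (is.na(cfg$outer_lower) | is.na(cfg$outer_upper)))) {
    abort("range_better components need `outer_lower` and `outer_upper`.")
  }
  invisible(cfg)
}

#' Score a single SHEI component
#'
#' Continuous, piecewise-linear scoring of one component value against its
#' reference interval (see [shei_config()] for the three direction types).
#'
#' @param value Component value(s) in the component's unit; must be
#'   non-negative. `NA` propagates to an `NA` score.
#' @param direction `"higher_better"`, `"lower_better"` or `"range_better"`.
#' @param lower_ref,upper_ref Reference interval.
#' @param outer_lower,outer_upper Outer zero-points for `range_better`.
#' @return Scores in `[0, 1]`.
#' @examples
#' shei_component_score(250, "higher_better", 0, 500) # 0.5
#' shei_component_score(12, "lower_better", 10, 20)   # 0.8
#' @export
shei_component_score <- function(value, direction, lower_ref, upper_ref,
                                 outer_lower = NA, outer_upper = NA) {
  if (any(value < 0, na.rm = TRUE)) {
    abort("SHEI component values must be non-negative.")
  }
  clamp01 <- function(x) pmin(pmax(x, 0), 1)
  switch(direction,
    higher_better = clamp01((value - lower_ref) / (upper_ref - lower_ref)),
    lower_better = clamp01((upper_ref - value) / (upper_ref - lower_ref)),
    range_better = {
      below <- clamp01((value - outer_lower) / (lower_ref - outer_lower))
      above <- clamp01((outer_upper - value) / (outer_upper - upper_ref))
      ifelse(is.na(value), NA_real_,
             ifelse(value < lower_ref, below,
                    ifelse(value > upper_ref, above, 1)))
    },
    abort(paste0("Unknown SHEI direction: ", direction))
  )
}

#' Swedish Healthy Eating Index scores for a cohort
#'
#' Computes the nine component scores (0-1 each) and the total (0-9) for
#' every participant x method row of a [participant_means()] table.
#'
#' @param participants Participant-intake tibble; must contain every column
#'   named in `config$column`.
#' @param config Component configuration, by default [shei_config()].
#' @param missing_policy What to do when a component input is `NA`:
#'   `"missing_total"` (default) leaves the total `NA`; `"rescale"` averages
#'   the available components and rescales to the 0-9 range.
#' @return A tibble with `participant_id`, `method`, one `score_<component>`
#'   column per component, and `shei_total`.
#' @examples
#' intake <- tibble::tibble(
#'   participant_id = "p1", method = "web_recall",
#'   fruit_veg_g = 500, wholegrain_g_10mj = 75, fibre_g_mj = 3,
#'   fish_shellfish_g = 40, pufa_epct = 7, mufa_epct = 15, sfa_epct = 9,
#'   red_processed_meat_weekly = 300, sucrose_epct = 8
#' )
#' shei_score(intake)$shei_total # 9
#' @export
shei_score <- function(participants, config = shei_config(),
                       missing_policy = c("missing_total", "rescale")) {
  missing_policy <- arg_match(missing_policy)
  validate_shei_config(config)
  missing <- setdiff(config$column, names(participants))
  if (length(missing)) {
    abort(paste0("`participants` is missing SHEI input column(s): ",
                 toString(missing)))
  }

  scores <- purrr::pmap(config, function(component, column, unit, direction,
                                         lower_ref, upper_ref,
                                         outer_lower, outer_upper, ...) {
    shei_component_score(participants[[column]], direction,
                         lower_ref, upper_ref, outer_lower, outer_upper)
  })
  names(scores) <- paste0("score_", config$component)
  score_mat <- as_tibble(scores)

  total <- rowSums(score_mat)
  if (missing_policy == "rescale") {
    k <- rowSums(!is.na(score_mat))
    total <- ifelse(k > 0, rowMeans(score_mat, na.rm = TRUE) * nrow(config),
                    NA_real_)
  }

  dplyr::bind_cols(
    participants[intersect(c("participant_id", "method"), names(participants))],
    score_mat,
    tibble(shei_total = total)
  )
}
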