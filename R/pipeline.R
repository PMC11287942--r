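#' Validate pipeline input tables
#'
#' Schema and content checks for the recall, composition, food-group and
#' (optional) isotope tables. Every finding carries a severity (`"error"`
#' blocks a run, `"warning"` does not), the table and row it refers to, and
#' a message.
#'
#' @param recalls,composition,foodgroups Dietary input tibbles (see
#'   [aggregate_days()]); pass file paths to have them read with
#'   [readr::read_csv()].
#' @param doses,urines Optional isotope tables (see [dlw_tee()]).
#' @return A tibble of findings: `severity`, `table`, `row`, `column`,
#'   `message`. Zero rows means a clean bill of health.
#' @export
validate_inputs <- function(recalls, composition, foodgroups,
                            doses = NULL, urines = NULL) {
  read_maybe <- function(x, name) {
    if (is.character(x)) {
      if (!file.exists(x)) {
        return(list(data = NULL, finding = finding_row(
          "error", name, NA, NA, paste0("File not readable: ", x)
        )))
      }
      x <- readr::read_csv(x, show_col_types = FALSE)
    }
    list(data = as_tibble(x), finding = NULL)
  }
  findings <- list()
  add <- function(f) findings[[length(findings) + 1]] <<- f

  tabs <- list(recalls = recalls, composition = composition,
               foodgroups = foodgroups, doses = doses, urines = urines)
  data <- list()
  for (nm in names(tabs)) {
    if (is.null(tabs[[nm]])) next
    got <- read_maybe(tabs[[nm]], nm)
    if (!is.null(got$finding)) add(got$finding)
    data[[nm]] <- got$data
  }

  req <- list(
    recalls = c("participant_id", "method", "day_index", "is_weekend",
                "food_code", "amount_g"),
    composition = c("food_code", NUTRIENT_COLS),
    foodgroups = c("food_code", "group"),
    doses = c("participant_id", "weight_kg", "dose_2h2o_g", "dose_h218o_g",
              "dose_enr_2h", "dose_enr_18o"),
    urines = c("participant_id", "time_days", "enr_2h", "enr_18o",
               "is_baseline")
  )
  for (nm in names(data)) {
    if (is.null(data[[nm]])) next
    miss <- setdiff(req[[nm]], names(data[[nm]]))
    for (col in miss) {
      add(finding_row("error", nm, NA, col, "Required column missing."))
    }
  }

  r <- data$recalls
  if (!is.null(r) && all(req$recalls %in% names(r))) {
    bad <- which(r$amount_g < 0)
    for (i in bad) {
      add(finding_row("error", "recalls", i, "amount_g",
                      "Negative amount."))
    }
    if (!is.null(data$composition) &&
        "food_code" %in% names(data$composition)) {
      unknown <- which(!r$food_code %in% data$composition$food_code)
      for (i in head(unknown, 20)) {
        add(finding_row("error", "recalls", i, "food_code",
                        paste0("Unknown food code: ", r$food_code[i])))
      }
    }
    dup <- r %>%
      distinct(.data$participant_id, .data$method, .data$day_index,
               .data$is_weekend) %>%
      count(.data$participant_id, .data$method, .data$day_index) %>%
      filter(.data$n > 1)
    if (nrow(dup)) {
      add(finding_row("error", "recalls", NA, "is_weekend",
                      "Conflicting is_weekend values within a day."))
    }
  }
  comp <- data$composition
  if (!is.null(comp) && all(req$composition %in% names(comp))) {
    for (col in NUTRIENT_COLS) {
      bad <- which(comp[[col]] < 0)
      for (i in bad) {
        add(finding_row("error", "composition", i, col, "Negative value."))
      }
      nas <- which(is.na(comp[[col]]))
      for (i in head(nas, 20)) {
        add(finding_row("warning", "composition", i, col,
                        "Missing nutrient value (treated as 0)."))
      }
    }
  }
  fgm <- data$foodgroups
  if (!is.null(fgm) && all(req$foodgroups %in% names(fgm))) {
    bad <- which(!fgm$group %in% FOOD_GROUPS)
    for (i in bad) {
      add(finding_row("error", "foodgroups", i, "group",
                      paste0("Unknown group label: ", fgm$group[i])))
    }
  }
  u <- data$urines
  if (!is.null(u) && all(req$urines %in% names(u))) {
    post <- u[!u$is_baseline, ]
    bad2h <- which(!u$is_baseline & u$enr_2h <= 0)
    bad18 <- which(!u$is_baseline & u$enr_18o <= 0)
    for (i in bad2h) {
      add(finding_row("error", "urines", i, "enr_2h",
                      "Non-positive post-dose enrichment."))
    }
    for (i in bad18) {
      add(finding_row("error", "urines", i, "enr_18o",
                      "Non-positive post-dose enrichment."))
    }
    n_post <- post %>% count(.data$participant_id)
    for (p in n_post$participant_id[n_post$n < 2]) {
      add(finding_row("error", "urines", NA, NA,
                      paste0("Fewer than 2 post-dose samples for ", p)))
    }
  }
  if (length(findings)) bind_rows(findings) else finding_row()[0, ]
}

finding_row <- function(severity = character(), table = character(),
                        row = integer(), column = character(),
                        message = character()) {
  tibble(severity = as.character(severity), table = as.character(table),
         row = as.integer(row), column = as.character(column),
         message = as.character(message))
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `recalls.csv`, `composition.csv`, `foodgroups.csv`, and (when the
#' DLW subsample is non-empty) `doses.csv` and `urines.csv`, plus the
#' `groundtruth.csv` sidecar, in the dialects [run_pipeline()] consumes.
#'
#' @param cohort A [generate_cohort()] result.
#' @param dir Output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(cohort$recalls, file.path(dir, "recalls.csv"))
  readr::write_csv(cohort$composition, file.path(dir, "composition.csv"))
  readr::write_csv(cohort$foodgroups, file.path(dir, "foodgroups.csv"))
  if (!is.null(cohort$doses)) {
    readr::write_csv(cohort$doses, file.path(dir, "doses.csv"))
    readr::write_csv(cohort$urines, file.path(dir, "urines.csv"))
  }
  readr::write_csv(cohort$ground_truth, file.path(dir, "groundtruth.csv"))
  invisible(dir)
}

#' Run the full validation pipeline on CSV inputs
#'
#' Reads the input tables from `input_dir`, validates them (any `"error"`
#' finding aborts before computation, and partial outputs are removed on
#' failure), then computes daily intakes, participant means, SHEI scores,
#' DLW results (when `doses.csv`/`urines.csv` are present; otherwise that
#' stage is skipped with a message), and the web-vs-telephone method
#' comparison. All outputs are written as tidy CSV into `output_dir`.
#'
#' @param input_dir Directory containing `recalls.csv`, `composition.csv`,
#'   `foodgroups.csv` and optionally `doses.csv` + `urines.csv`.
#' @param output_dir Where to write results (created if needed).
#' @param shei_cfg SHEI component configuration tibble.
#' @param constants [dlw_constants()].
#' @param food_quotient Diet food quotient for the DLW stage.
#' @param compare_variables Variables for the method-comparison table.
#' @return Invisibly, a list with every computed table (`daily`,
#'   `participants`, `shei`, `dlw`, `comparison`, `findings`).
#' @export
run_pipeline <- function(input_dir, output_dir = file.path(input_dir, "out"),
                         shei_cfg = shei_config(),
                         constants = dlw_constants(), food_quotient = 0.86,
                         compare_variables = c(
                           "energy_kj", "protein_epct", "fat_epct",
                           "carbohydrate_epct", "sucrose_epct",
                           paste0(FOOD_GROUPS, "_g"), "shei_total"
                         )) {
  path <- function(f) file.path(input_dir, f)
  has_dlw <- file.exists(path("doses.csv")) && file.exists(path("urines.csv"))

  findings <- validate_inputs(
    recalls = path("recalls.csv"), composition = path("composition.csv"),
    foodgroups = path("foodgroups.csv"),
    doses = if (has_dlw) path("doses.csv"),
    urines = if (has_dlw) path("urines.csv")
  )
  if (any(findings$severity == "error")) {
    abort(paste0(
      "Input validation failed with ", sum(findings$severity == "error"),
      " error(s); first: ",
      findings$message[findings$severity == "error"][1]
    ))
  }

  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character()
  emit <- function(x, name) {
    f <- file.path(output_dir, name)
    readr::write_csv(x, f)
    written <<- c(written, f)
  }
  on_failure <- function(e) {
    unlink(written)
    abort(paste0("Pipeline failed; partial outputs removed. ",
                 conditionMessage(e)))
  }

  tryCatch({
    recalls <- readr::read_csv(path("recalls.csv"), show_col_types = FALSE)
    composition <- readr::read_csv(path("composition.csv"),
                                   show_col_types = FALSE)
    foodgroups <- readr::read_csv(path("foodgroups.csv"),
                                  show_col_types = FALSE)

    daily <- aggregate_days(recalls, composition, foodgroups)
    n_flagged <- sum(daily$flag != "ok")
    if (n_flagged) {
      inform(paste0(n_flagged, " day(s) flagged by the energy ",
                    "plausibility screen (retained)."))
    }
    participants <- participant_means(daily)
    shei <- shei_score(participants, shei_cfg)
    participants_full <- participants %>%
      left_join(select(shei, "participant_id", "method", "shei_total"),
                by = c("participant_id", "method"))

    emit(daily, "daily_intakes.csv")
    emit(participants_full, "participant_intakes.csv")
    emit(shei, "shei_scores.csv")

    dlw <- NULL
    if (has_dlw) {
      doses <- readr::read_csv(path("doses.csv"), show_col_types = FALSE)
      urines <- readr::read_csv(path("urines.csv"), show_col_types = FALSE)
      dlw <- dlw_tee(doses, urines, food_quotient = food_quotient,
                     constants = constants)
      emit(as_tibble(dlw), "dlw_results.csv")
    } else {
      inform("No isotope files found; DLW stage skipped.")
    }

    methods <- intersect(ASSESSMENT_METHODS, unique(participants_full$method))
    comparison <- NULL
    if (length(methods) == 2) {
      a <- filter(participants_full, .data$method == "web_recall")
      b <- filter(participants_full, .data$method == "telephone_recall")
      vars <- intersect(compare_variables, names(participants_full))
      comparison <- compare_methods(a, b, vars)
      emit(as_tibble(comparison), "comparison_summary.csv")
      ba_energy <- augment(attr(comparison, "ba")[["energy_kj"]])
      emit(ba_energy, "blandaltman_energy_kj.csv")
    }

    invisible(list(daily = daily, participants = participants_full,
                   shei = shei, dlw = dlw, comparison = comparison,
                   findings = findings, output_dir = output_dir))
  }, error = on_failure)
}
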