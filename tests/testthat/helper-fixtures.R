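# Small hand-built tables used across test files. All values chosen so that
# expected totals can be verified by simple row-wise arithmetic.

fixture_composition <- function() {
  tibble::tibble(
    food_code = c("APPLE", "SALMON", "BREAD", "SODA"),
    energy_kj = c(220, 830, 1030, 180),
    protein_g = c(0.3, 20, 9, 0),
    fat_g = c(0.2, 13, 3, 0),
    carbohydrate_g = c(11.5, 0, 45, 10.5),
    sucrose_g = c(8, 0, 2, 10.5),
    fibre_g = c(2, 0, 6, 0),
    wholegrain_g = c(0, 0, 40, 0),
    pufa_g = c(0.05, 3.5, 1, 0),
    mufa_g = c(0.05, 5, 0.8, 0),
    sfa_g = c(0.05, 2.5, 0.6, 0)
  )
}

fixture_foodgroups <- function() {
  tibble::tibble(
    food_code = c("APPLE", "SALMON", "SODA"),
    group = c("fruit_veg", "fish_shellfish", "ssb")
  )
}

fixture_recalls <- function() {
  tibble::tibble(
    participant_id = "p1",
    method = "web_recall",
    day_index = 1L,
    is_weekend = FALSE,
    food_code = c("APPLE", "SALMON", "BREAD"),
    amount_g = c(150, 120, 80)
  )
}

# independent spreadsheet-style oracle: per-food row-wise sums
fixture_day_oracle <- function(recalls = fixture_recalls(),
                               composition = fixture_composition()) {
  merged <- merge(recalls, composition, by = "food_code")
  cols <- c("energy_kj", "protein_g", "fat_g", "carbohydrate_g", "sucrose_g",
            "fibre_g", "wholegrain_g", "pufa_g", "mufa_g", "sfa_g")
  sapply(cols, function(col) sum(merged[[col]] * merged$amount_g / 100))
}

# a participant-intake record meeting every SHEI component target
optimal_intake <- function() {
  tibble::tibble(
    participant_id = "opt", method = "web_recall",
    fruit_veg_g = 600, wholegrain_g_10mj = 80, fibre_g_mj = 3.5,
    fish_shellfish_g = 50, pufa_epct = 7, mufa_epct = 15, sfa_epct = 8,
    red_processed_meat_weekly = 200, sucrose_epct = 5
  )
}

# a record at (or beyond) every worst bound
worst_intake <- function() {
  tibble::tibble(
    participant_id = "worst", method = "web_recall",
    fruit_veg_g = 0, wholegrain_g_10mj = 0, fibre_g_mj = 0,
    fish_shellfish_g = 0, pufa_epct = 0, mufa_epct = 0, sfa_epct = 25,
    red_processed_meat_weekly = 900, sucrose_epct = 25
  )
}

# random non-negative intake record for property tests
random_intake <- function(n = 1) {
  tibble::tibble(
    participant_id = sprintf("r%d", seq_len(n)), method = "web_recall",
    fruit_veg_g = runif(n, 0, 900),
    wholegrain_g_10mj = runif(n, 0, 120),
    fibre_g_mj = runif(n, 0, 5),
    fish_shellfish_g = runif(n, 0, 120),
    pufa_epct = runif(n, 0, 20),
    mufa_epct = runif(n, 0, 35),
    sfa_epct = runif(n, 0, 30),
    red_processed_meat_weekly = runif(n, 0, 1500),
    sucrose_epct = runif(n, 0, 30)
  )
}

# noise-free urine series from known kinetics
fixture_urines <- function(e0_d = 150, e0_o = 120, k_d = 0.09, k_o = 0.11,
                           id = "p1", days = c(1, 5, 8, 12, 15)) {
  tibble::tibble(
    participant_id = id,
    time_days = c(-2, -1, days),
    enr_2h = c(0, 0, e0_d * exp(-k_d * days)),
    enr_18o = c(0, 0, e0_o * exp(-k_o * days)),
    is_baseline = c(TRUE, TRUE, rep(FALSE, length(days)))
  )
}

# closed-form OLS of y on x (normal equations), independent of lm()
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  c(slope = slope, intercept = intercept)
}

# exact paired-Wilcoxon p by enumerating all sign assignments (no ties/zeros)
wilcoxon_enum_oracle <- function(d) {
  stopifnot(all(d != 0), !any(duplicated(abs(d))))
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  v_all <- signs %*% r
  mean(abs(v_all - n * (n + 1) / 4) >= abs(v_obs - n * (n + 1) / 4) - 1e-12)
}
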