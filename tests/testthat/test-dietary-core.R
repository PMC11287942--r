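test_that("day aggregation is proportional and matches a row-wise oracle", {
  comp <- tibble::tibble(
    food_code = "X", energy_kj = 500, protein_g = 10, fat_g = 5,
    carbohydrate_g = 8, sucrose_g = 2, fibre_g = 3, wholegrain_g = 1,
    pufa_g = 1, mufa_g = 2, sfa_g = 1.5
  )
  fgm <- tibble::tibble(food_code = "X", group = "fruit_veg")
  day <- aggregate_day(
    tibble::tibble(food_code = "X", amount_g = 200), comp, fgm
  )
  expect_equal(day$energy_kj, 1000)
  expect_equal(day$protein_g, 20)
  expect_equal(day$fruit_veg_g, 200)

  # 3-item fixture against the independent spreadsheet-style sum
  oracle <- fixture_day_oracle()
  day3 <- aggregate_day(fixture_recalls()[, c("food_code", "amount_g")],
                        fixture_composition(), fixture_foodgroups())
  for (col in names(oracle)) {
    expect_equal(day3[[col]], unname(oracle[col]), info = col)
  }
  # groups absent from the day are 0, not missing
  expect_equal(day3$ssb_g, 0)
  expect_equal(day3$fish_shellfish_g, 120)
})

test_that("an empty day is valid, all-zero, and flagged low", {
  day <- aggregate_day(
    tibble::tibble(food_code = character(), amount_g = numeric()),
    fixture_composition(), fixture_foodgroups()
  )
  expect_equal(nrow(day), 1)
  expect_equal(day$energy_kj, 0)
  expect_equal(day$fruit_veg_g, 0)
  expect_equal(day$flag, "low")
  expect_true(is.na(day$protein_epct)) # E% undefined at zero energy
})

test_that("unresolvable food codes are a hard error naming the code", {
  recalls <- fixture_recalls()
  recalls$food_code[2] <- "MYSTERY"
  expect_error(
    aggregate_days(recalls, fixture_composition(), fixture_foodgroups()),
    "MYSTERY"
  )
})

test_that("energy_percent handles round numbers, zero nutrient, zero energy", {
  expect_equal(energy_percent(50, 17, 8500), 10)
  expect_equal(energy_percent(0, 37, 8500), 0)
  expect_true(is.na(energy_percent(50, 17, 0)))
  expect_error(energy_percent(-1, 17, 1000), "non-negative")
  # fixture day: hand-checked protein E%
  oracle <- fixture_day_oracle()
  expect_equal(
    energy_percent(oracle["protein_g"], 17, oracle["energy_kj"]),
    unname(100 * oracle["protein_g"] * 17 / oracle["energy_kj"]),
    ignore_attr = TRUE
  )
})

test_that("plausibility flags use strict kcal thresholds", {
  kj <- function(kcal) kcal * 4.184
  expect_equal(plausibility_flag(kj(3600)), "high")
  expect_equal(plausibility_flag(kj(2000)), "ok")
  expect_equal(plausibility_flag(kj(3500)), "ok") # 'exceeded' is strict
  expect_equal(plausibility_flag(kj(800)), "ok")
  expect_equal(plausibility_flag(kj(799)), "low")
})

test_that("participant means average days and derive weekly meat", {
  comp <- fixture_composition()
  fgm <- fixture_foodgroups()
  recalls <- dplyr::bind_rows(
    fixture_recalls(),
    dplyr::mutate(fixture_recalls(), day_index = 2L, amount_g = amount_g * 2)
  )
  daily <- aggregate_days(recalls, comp, fgm)
  pm <- participant_means(daily)
  expect_equal(pm$n_days, 2)
  expect_equal(pm$energy_kj, mean(daily$energy_kj))
  expect_equal(pm$red_processed_meat_weekly,
               7 * (pm$red_meat_g + pm$processed_meat_g))

  # idempotence on identical days
  daily2 <- daily
  daily2$energy_kj <- c(8000, 10000)
  expect_equal(participant_means(daily2)$energy_kj, 9000)

  expect_error(participant_means(daily[0, ]))
})

test_that("cohort summary equals the two-point mean/SD and an oracle", {
  pm <- tibble::tibble(
    participant_id = c("a", "b"), method = "web_recall", n_days = 3,
    energy_kj = c(9000, 11000), red_meat_g = c(10, 30),
    processed_meat_g = c(0, 0),
    red_processed_meat_weekly = 7 * c(10, 30)
  )
  cs <- cohort_summary(pm, variables = "energy_kj")
  expect_equal(cs$mean, 10000)
  expect_equal(cs$sd, sqrt(sum((c(9000, 11000) - 10000)^2) / 1), tolerance = 1e-12)
  expect_equal(round(cs$sd, 1), 1414.2)
  expect_error(cohort_summary(pm[1, ]), "at least 2")
})

test_that("aggregation is linear, scale-equivariant and order-invariant", {
  comp <- fixture_composition()
  fgm <- fixture_foodgroups()
  set.seed(42)
  for (i in 1:5) {
    items1 <- tibble::tibble(
      food_code = sample(comp$food_code, 3, replace = TRUE),
      amount_g = runif(3, 10, 300)
    )
    items2 <- tibble::tibble(
      food_code = sample(comp$food_code, 2, replace = TRUE),
      amount_g = runif(2, 10, 300)
    )
    both <- dplyr::bind_rows(items1, items2)
    d1 <- aggregate_day(items1, comp, fgm)
    d2 <- aggregate_day(items2, comp, fgm)
    d12 <- aggregate_day(both, comp, fgm)
    num <- c("energy_kj", "protein_g", "fruit_veg_g", "ssb_g")
    for (col in num) {
      expect_equal(d12[[col]], d1[[col]] + d2[[col]], info = col)
    }
    # scaling amounts by c scales masses, leaves E% unchanged
    dc <- aggregate_day(dplyr::mutate(both, amount_g = amount_g * 2.5),
                        comp, fgm)
    expect_equal(dc$energy_kj, 2.5 * d12$energy_kj)
    expect_equal(dc$protein_epct, d12$protein_epct)
    expect_equal(dc$fibre_g_mj, d12$fibre_g_mj)
    # permutation invariance
    dp <- aggregate_day(both[sample(nrow(both)), ], comp, fgm)
    expect_equal(dp$energy_kj, d12$energy_kj)
    expect_equal(dp$fruit_veg_g, d12$fruit_veg_g)
  }
})

test_that("participant_mean commutes with field selection", {
  co <- generate_cohort(cohort_config(n_participants = 4, n_dlw = 0), seed = 7)
  daily <- aggregate_days(co$recalls, co$composition, co$foodgroups)
  pm <- participant_means(daily)
  manual <- daily %>%
    dplyr::group_by(participant_id, method) %>%
    dplyr::summarise(energy_kj = mean(energy_kj), .groups = "drop")
  merged <- dplyr::inner_join(pm, manual, by = c("participant_id", "method"),
                              suffix = c("", "_manual"))
  expect_equal(merged$energy_kj, merged$energy_kj_manual)
})

test_that("flagged days can be excluded via the config switch", {
  daily <- tibble::tibble(
    participant_id = "p1", method = "web_recall", day_index = 1:2,
    is_weekend = FALSE,
    energy_kj = c(2000, 9000), red_meat_g = c(0, 10),
    processed_meat_g = c(0, 0),
    flag = plausibility_flag(c(2000, 9000))
  )
  expect_equal(participant_means(daily)$n_days, 2)
  kept <- participant_means(daily, exclude_flagged = TRUE)
  expect_equal(kept$n_days, 1)
  expect_equal(kept$energy_kj, 9000)
})
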