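test_that("noise-free exponentials are recovered to machine precision", {
  u <- fixture_urines(e0_d = 150, e0_o = 120, k_d = 0.1, k_o = 0.1)
  fit <- fit_elimination(u)
  expect_equal(fit$k, c(0.1, 0.1), tolerance = 1e-12)
  expect_equal(fit$zero_time_excess, c(150, 120), tolerance = 1e-9)
  expect_equal(fit$r_squared, c(1, 1), tolerance = 1e-12)
  expect_equal(fit$n_points, c(5L, 5L))

  # two points only
  u2 <- tibble::tibble(
    participant_id = "p1", time_days = c(-1, 0, 1, 5),
    enr_2h = c(0, 0, exp(-0.1), exp(-0.5)),
    enr_18o = c(0, 0, exp(-0.12), exp(-0.6)),
    is_baseline = c(TRUE, TRUE, FALSE, FALSE)
  )
  fit2 <- fit_elimination(u2, isotope = "2H")
  expect_equal(fit2$k, 0.1, tolerance = 1e-12)
})

test_that("elimination fit equals the closed-form OLS oracle on noisy data", {
  set.seed(31)
  for (i in 1:10) {
    days <- c(1, 5, 8, 12, 15)
    k <- runif(1, 0.07, 0.13)
    e0 <- runif(1, 80, 200)
    noise <- exp(rnorm(5, 0, 0.02))
    enr <- e0 * exp(-k * days) * noise
    u <- tibble::tibble(
      participant_id = "p", time_days = c(-2, -1, days),
      enr_2h = c(0, 0, enr), enr_18o = c(0, 0, enr),
      is_baseline = c(TRUE, TRUE, rep(FALSE, 5))
    )
    fit <- fit_elimination(u, isotope = "2H")
    oracle <- ols_oracle(days, log(enr))
    expect_equal(fit$k, -unname(oracle["slope"]), tolerance = 1e-10)
    expect_equal(fit$zero_time_excess, exp(unname(oracle["intercept"])),
                 tolerance = 1e-10)
  }
})

test_that("baseline subtraction uses the mean of the pre-dose samples", {
  u <- fixture_urines(e0_d = 150, e0_o = 120, k_d = 0.09, k_o = 0.11)
  u$enr_2h <- u$enr_2h + c(4, 6, rep(5, 5)) # constant 5-unit baseline shift
  u$enr_18o <- u$enr_18o + c(2, 4, rep(3, 5))
  fit <- fit_elimination(u)
  expect_equal(fit$k, c(0.09, 0.11), tolerance = 1e-12)
  expect_equal(fit$zero_time_excess, c(150, 120), tolerance = 1e-9)
})

test_that("degenerate elimination inputs are rejected with context", {
  u <- fixture_urines()
  u$enr_2h[4] <- -1
  expect_error(fit_elimination(u, isotope = "2H"), "p1.*day 5")
  u3 <- fixture_urines(days = 1)
  expect_error(fit_elimination(u3, isotope = "2H"), ">= 2 post-dose")
})

test_that("dilution space scales with dose and inversely with intercept", {
  n0 <- dilution_space(10, 1e5, 30, 20.02)
  expect_equal(dilution_space(20, 1e5, 30, 20.02), 2 * n0)
  expect_equal(dilution_space(10, 1e5, 60, 20.02), n0 / 2)
  expect_equal(n0, (10 / 20.02) * 1e5 / 30)
  expect_error(dilution_space(10, 1e5, 0, 20.02), "positive")
  expect_error(dilution_space(0, 1e5, 30, 20.02), "positive")
})

test_that("the two-pool CO2 equation matches a hand-evaluated oracle", {
  k <- dlw_constants()
  # cancellation point: fractionation-weighted rates equal -> rCO2 = 0
  k_d <- 0.1
  k_o <- k$frac_d * k_d / k$frac_o
  expect_equal(co2_production(2000, 2000, k_d, k_o), 0)
  # hand-evaluated arithmetic at N = 2000, k_o = 0.12, k_d = 0.10
  n_pool <- (2000 / 1.0427 + 2000) / 2
  expected <- n_pool * (1.007 * 0.12 - 1.041 * 0.10) *
    (1 / 2.078 - 0.0246 * 1.05)
  expect_equal(co2_production(2000, 2000, 0.10, 0.12), expected,
               tolerance = 1e-12)
  # homogeneity in the pool sizes
  expect_equal(co2_production(3000, 3000, 0.10, 0.12), 1.5 * expected)
  # oxygen must turn over faster
  expect_error(co2_production(2000, 2000, 0.12, 0.10), "Non-physiological")
})

test_that("the energy equivalent of CO2 follows the Weir expression", {
  k <- dlw_constants()
  expect_equal(energy_equivalent(1.0), (3.941 + 1.106) * 4.184)
  expect_equal(energy_equivalent(0.86),
               (k$weir_a / 0.86 + k$weir_b) * k$kcal_to_kj)
  # strictly decreasing in FQ
  fq <- seq(0.7, 1.0, by = 0.05)
  expect_true(all(diff(energy_equivalent(fq)) < 0))
  expect_error(energy_equivalent(0.5), "0.7")
  expect_error(energy_equivalent(1.2), "0.7")
})

test_that("dlw_tee equals the manual composition of its four stages", {
  cfg <- cohort_config(n_participants = 3, n_dlw = 3,
                       enrichment_noise_cv = 0)
  co <- generate_cohort(cfg, seed = 21)
  res <- dlw_tee(co$doses, co$urines)
  k <- dlw_constants()
  fits <- fit_elimination(co$urines)
  p1 <- res$participant_id[1]
  f_d <- fits[fits$participant_id == p1 & fits$isotope == "2H", ]
  f_o <- fits[fits$participant_id == p1 & fits$isotope == "18O", ]
  dose <- co$doses[co$doses$participant_id == p1, ]
  n_d <- dilution_space(dose$dose_2h2o_g, dose$dose_enr_2h,
                        f_d$zero_time_excess, k$molar_mass_2h2o)
  n_o <- dilution_space(dose$dose_h218o_g, dose$dose_enr_18o,
                        f_o$zero_time_excess, k$molar_mass_h218o)
  rco2 <- co2_production(n_d, n_o, f_d$k, f_o$k)
  tee_manual <- rco2 * k$molar_volume_l * energy_equivalent(0.86)
  expect_equal(res$tee_kj[1], tee_manual, tolerance = 1e-12)
})

test_that("noise-free simulation round-trips kinetics and TEE", {
  cfg <- cohort_config(n_participants = 8, n_dlw = 8,
                       enrichment_noise_cv = 0)
  co <- generate_cohort(cfg, seed = 22)
  res <- dlw_tee(co$doses, co$urines)
  gt <- dplyr::inner_join(co$ground_truth, res, by = "participant_id")
  expect_true(all(abs(gt$k_d.x - gt$k_d.y) / gt$k_d.x < 1e-3))
  expect_true(all(abs(gt$k_o.x - gt$k_o.y) / gt$k_o.x < 1e-3))
  expect_true(all(abs(gt$n_d.x - gt$n_d.y) / gt$n_d.x < 1e-3))
  expect_true(all(abs(gt$n_o.x - gt$n_o.y) / gt$n_o.x < 1e-3))
  expect_true(all(abs(gt$tee_kj.y - gt$tee_kj.x) / gt$tee_kj.x < 5e-3))
})

test_that("enrichment noise propagates to TEE within the expected envelope", {
  # TEE rests on the difference of two similar elimination rates, so
  # per-sample enrichment noise is amplified roughly four-fold: 1% noise
  # keeps the median TEE error under 5%; at the default 1.5% the error
  # grows proportionally and must stay under 10%.
  run_sims <- function(cv, seeds) {
    errs <- c(); ratios <- c()
    for (s in seeds) {
      cfg <- cohort_config(n_participants = 8, n_dlw = 8,
                           enrichment_noise_cv = cv)
      co <- generate_cohort(cfg, seed = s)
      res <- dlw_tee(co$doses, co$urines)
      gt <- dplyr::inner_join(co$ground_truth, res, by = "participant_id")
      errs <- c(errs, abs(gt$tee_kj.y - gt$tee_kj.x) / gt$tee_kj.x)
      ratios <- c(ratios, res$dilution_space_ratio)
    }
    list(errs = errs, ratios = ratios)
  }
  lo <- run_sims(0.01, 500 + 1:10)
  expect_lt(median(lo$errs), 0.05)
  hi <- run_sims(0.015, 100 + 1:10)
  expect_lt(median(hi$errs), 0.10)
  # observed dilution-space ratios bracket the generator value
  expect_true(min(hi$ratios) < 1.035 && max(hi$ratios) > 1.035)
})

test_that("the simulated cohort dilution-space ratio centres on 1.035", {
  cfg <- cohort_config(n_participants = 24, n_dlw = 24,
                       enrichment_noise_cv = 0.005)
  co <- generate_cohort(cfg, seed = 23)
  res <- dlw_tee(co$doses, co$urines)
  se <- sd(res$dilution_space_ratio) / sqrt(nrow(res))
  expect_lt(abs(mean(res$dilution_space_ratio) - 1.035), 2 * se + 1e-9)
  expect_true(all(res$dsr_qc %in% c("ok", "flag")))
})
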