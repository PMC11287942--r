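# brute-force oracle for every Bland-Altman field, explicit formulas only
ba_oracle <- function(a, b) {
  d <- a - b
  m <- (a + b) / 2
  n <- length(d)
  mean_diff <- sum(d) / n
  sd_diff <- sqrt(sum((d - mean_diff)^2) / (n - 1))
  sl <- ols_oracle(m, d)
  r_num <- sum((m - mean(m)) * (d - mean(d)))
  r <- r_num / sqrt(sum((m - mean(m))^2) * sum((d - mean(d))^2))
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  p <- 2 * stats::pt(-abs(tstat), df = n - 2)
  list(mean_diff = mean_diff, sd_diff = sd_diff,
       loa = c(mean_diff - 2 * sd_diff, mean_diff + 2 * sd_diff),
       slope = unname(sl["slope"]), intercept = unname(sl["intercept"]),
       r = r, p = p, pct = 100 * mean_diff / mean(b))
}

test_that("identical series give zero differences and a degenerate fit", {
  d <- tibble::tibble(a = c(3, 5, 9, 11), b = c(3, 5, 9, 11))
  ba <- bland_altman(d, a, b)
  expect_equal(ba$stats$mean_diff, 0)
  expect_equal(ba$stats$loa_lower, 0)
  expect_equal(ba$stats$loa_upper, 0)
  expect_equal(ba$stats$slope, 0)
  expect_true(is.na(ba$stats$r))
})

test_that("the hand-arithmetic example reproduces exactly", {
  d <- tibble::tibble(a = c(1, 2, 3), b = c(0, 0, 0))
  ba <- bland_altman(d, a, b)
  expect_equal(ba$stats$mean_diff, 2)
  expect_equal(ba$stats$sd_diff, 1)
  expect_equal(ba$stats$loa_lower, 0)
  expect_equal(ba$stats$loa_upper, 4)
})

test_that("all Bland-Altman fields equal the formula oracle on seeded pairs", {
  set.seed(41)
  for (i in 1:5) {
    a <- rnorm(10, 100, 15)
    b <- rnorm(10, 95, 12)
    ba <- bland_altman(tibble::tibble(a = a, b = b), a, b)
    o <- ba_oracle(a, b)
    expect_equal(ba$stats$mean_diff, o$mean_diff, tolerance = 1e-12)
    expect_equal(ba$stats$sd_diff, o$sd_diff, tolerance = 1e-12)
    expect_equal(c(ba$stats$loa_lower, ba$stats$loa_upper), o$loa,
                 tolerance = 1e-12)
    expect_equal(ba$stats$slope, o$slope, tolerance = 1e-10)
    expect_equal(ba$stats$intercept, o$intercept, tolerance = 1e-10)
    expect_equal(ba$stats$r, o$r, tolerance = 1e-12)
    expect_equal(ba$stats$p_value, o$p, tolerance = 1e-12)
    expect_equal(ba$stats$mean_diff_pct, o$pct, tolerance = 1e-12)
  }
})

test_that("swapping the series negates the mean difference, SD unchanged", {
  set.seed(42)
  a <- rnorm(15, 50, 5); b <- rnorm(15, 48, 6)
  d <- tibble::tibble(a = a, b = b)
  ab <- bland_altman(d, a, b)
  ba <- bland_altman(d, b, a)
  expect_equal(ab$stats$mean_diff, -ba$stats$mean_diff)
  expect_equal(ab$stats$sd_diff, ba$stats$sd_diff)
})

test_that("percentage reference switches between series b and the average", {
  d <- tibble::tibble(a = c(12, 14, 16), b = c(10, 10, 10))
  ba_b <- bland_altman(d, a, b, reference = "series_b")
  ba_m <- bland_altman(d, a, b, reference = "mean_of_both")
  expect_equal(ba_b$stats$mean_diff_pct, 100 * 4 / 10)
  expect_equal(ba_m$stats$mean_diff_pct, 100 * 4 / 12)
})

test_that("paired t behaves under symmetry, shift, and the closed form", {
  d <- tibble::tibble(a = c(1, 2, 1, 2), b = c(2, 1, 2, 1))
  res <- paired_location_test(d, a, b, family = "t")
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)

  set.seed(43)
  av <- rnorm(12, 10, 2)
  shift <- tibble::tibble(a = av, b = av + 5)
  res2 <- paired_location_test(shift, a, b, family = "t")
  expect_equal(res2$mean_diff, -5)
  expect_lt(res2$p_value, 1e-6)

  # closed-form oracle t = mean_diff / (sd_diff / sqrt(n))
  x <- rnorm(10); y <- rnorm(10)
  res3 <- paired_location_test(tibble::tibble(a = x, b = y), a, b,
                               family = "t")
  dd <- x - y
  expect_equal(res3$statistic, mean(dd) / (sd(dd) / sqrt(10)),
               tolerance = 1e-12)
})

test_that("the exact Wilcoxon p equals the sign-enumeration oracle", {
  set.seed(44)
  for (i in 1:3) {
    d <- round(rnorm(9, 0.3, 1), 3)
    d <- d[d != 0][!duplicated(abs(d))]
    df <- tibble::tibble(a = d, b = 0)
    res <- paired_location_test(df, a, b, family = "wilcoxon")
    expect_equal(res$p_value, wilcoxon_enum_oracle(d), tolerance = 1e-10)
  }
})

test_that("all-zero differences return p = 1 by convention", {
  d <- tibble::tibble(a = c(1, 2, 3, 4, 5), b = c(1, 2, 3, 4, 5))
  expect_message(res <- paired_location_test(d, a, b, family = "wilcoxon"),
                 "convention")
  expect_equal(res$p_value, 1)
})

test_that("correlations respect affine maps and monotone transforms", {
  set.seed(45)
  x <- rnorm(20, 5, 2)
  d <- tibble::tibble(a = x, b = 2 * x + 1)
  expect_equal(paired_correlation(d, a, b, family = "pearson")$r, 1,
               tolerance = 1e-12)
  xp <- runif(20, 1, 10)
  d2 <- tibble::tibble(a = xp, b = xp^2)
  expect_equal(paired_correlation(d2, a, b, family = "spearman")$r, 1,
               tolerance = 1e-12)
  expect_lt(paired_correlation(d2, a, b, family = "pearson")$r, 1)
  # textbook sum-formula oracle for Pearson r
  y <- rnorm(20, 3, 1)
  r_impl <- paired_correlation(tibble::tibble(a = x, b = y), a, b,
                               family = "pearson")$r
  n <- 20
  r_oracle <- (n * sum(x * y) - sum(x) * sum(y)) /
    sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  expect_equal(r_impl, r_oracle, tolerance = 1e-12)
})

test_that("zero-variance series yield a missing correlation with warning", {
  d <- tibble::tibble(a = c(1, 1, 1), b = c(1, 2, 3))
  expect_warning(res <- paired_correlation(d, a, b, family = "pearson"),
                 "variance")
  expect_true(is.na(res$r))
})

test_that("the normality rule picks the right family and obeys overrides", {
  set.seed(46)
  picks_normal <- replicate(100, choose_family(rnorm(50)))
  expect_gte(mean(picks_normal == "parametric"), 0.9)
  picks_heavy <- replicate(100, choose_family(rlnorm(50, 0, 1)))
  expect_gte(mean(picks_heavy == "nonparametric"), 0.9)
  # forced override honoured regardless of data
  heavy <- tibble::tibble(a = rlnorm(30, 0, 1), b = rlnorm(30, 0, 1))
  expect_equal(paired_location_test(heavy, a, b, family = "t")$family, "t")
  expect_equal(paired_correlation(heavy, a, b, family = "pearson")$family,
               "pearson")
})

test_that("self-comparison yields zero differences and perfect correlation", {
  set.seed(47)
  pm <- tibble::tibble(
    participant_id = sprintf("p%d", 1:12),
    energy_kj = rnorm(12, 10000, 1500),
    protein_epct = rnorm(12, 15, 2)
  )
  cmp <- compare_methods(pm, pm, c("energy_kj", "protein_epct"))
  expect_equal(cmp$mean_diff, c(0, 0))
  expect_equal(cmp$r, c(1, 1))
  expect_equal(cmp$p_diff, c(1, 1))
  # table completeness: every requested variable exactly once
  expect_equal(sort(cmp$variable), sort(c("energy_kj", "protein_epct")))
})

test_that("unmatched participants are dropped with a message", {
  set.seed(48)
  a <- tibble::tibble(participant_id = sprintf("p%d", 1:10),
                      energy_kj = rnorm(10, 10000, 1000))
  b <- tibble::tibble(participant_id = sprintf("p%d", 3:14),
                      energy_kj = rnorm(12, 10000, 1000))
  expect_message(cmp <- compare_methods(a, b, "energy_kj"), "unmatched")
  expect_equal(cmp$n, 8)
})

test_that("LoA cover about 95% of normal differences", {
  set.seed(49)
  cover <- replicate(100, {
    d <- tibble::tibble(a = rnorm(52), b = 0)
    mean(augment(bland_altman(d, a, b))$within_loa)
  })
  expect_lt(abs(mean(cover) - 0.954), 0.01)
})

test_that("broom and plot methods work on a Bland-Altman object", {
  set.seed(50)
  d <- tibble::tibble(a = rnorm(20, 100, 10), b = rnorm(20, 98, 10))
  ba <- bland_altman(d, a, b)
  td <- tidy(ba)
  expect_true(all(c("term", "estimate") %in% names(td)))
  expect_equal(nrow(glance(ba)), 1)
  aug <- augment(ba)
  expect_equal(nrow(aug), 20)
  expect_s3_class(autoplot(ba), "ggplot")
})
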