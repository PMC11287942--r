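#' Bland-Altman agreement analysis for two paired measurement series
#'
#' Computes the per-pair differences `a - b` and averages `(a + b)/2`, the
#' mean difference, its SD (n - 1 denominator), limits of agreement as the
#' mean difference +/- `loa_multiplier` SD, the difference-on-average
#' regression (OLS slope, intercept, Pearson r and two-sided p) used to
#' detect proportional bias, and the mean difference as a percentage of a
#' reference level.
#'
#' @param data A data frame with one row per participant.
#' @param a,b Columns (tidyselect) holding the two methods' values;
#'   `a` is the method under evaluation, `b` the comparison method.
#' @param reference Denominator of the percentage mean difference:
#'   `"series_b"` (default; e.g. mean TEE when validating energy intake
#'   against doubly labelled water) or `"mean_of_both"`.
#' @param loa_multiplier SD multiplier for the limits of agreement;
#'   default 2 (mean difference +/- 2 SD).
#' @param variable Optional label carried into the output.
#' @return An object of class `bland_altman`: a list with `stats` (one-row
#'   tibble: `n`, `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `loa_half_width`, `slope`, `intercept`, `r`, `p_value`,
#'   `mean_diff_pct`) and `data` (per-pair `a`, `b`, `diff`, `avg`).
#'   Supports [tidy()], [glance()], [augment()] and [autoplot()].
#' @examples
#' d <- tibble::tibble(x = c(1, 2, 3), y = c(0, 0, 0))
#' glance(bland_altman(d, x, y))
#' @export
bland_altman <- function(data, a, b,
                         reference = c("series_b", "mean_of_both"),
                         loa_multiplier = 2, variable = NULL) {
  reference <- arg_match(reference)
  a_vals <- dplyr::pull(data, {{ a }})
  b_vals <- dplyr::pull(data, {{ b }})
  keep <- stats::complete.cases(a_vals, b_vals)
  a_vals <- a_vals[keep]
  b_vals <- b_vals[keep]
  n <- length(a_vals)
  if (n < 3) abort("Bland-Altman analysis needs at least 3 complete pairs.")

  diffs <- a_vals - b_vals
  avgs <- (a_vals + b_vals) / 2
  mean_diff <- mean(diffs)
  sd_diff <- sd(diffs)

  if (sd(avgs) > 0) {
    fit <- lm(diffs ~ avgs)
    slope <- unname(coef(fit)[2])
    intercept <- unname(coef(fit)[1])
    if (sd_diff > 0) {
      ct <- cor.test(avgs, diffs)
      r <- unname(ct$estimate)
      p <- ct$p.value
    } else {
      # identical-difference series: flat regression, correlation undefined
      r <- NA_real_
      p <- NA_real_
    }
  } else {
    warn("Zero variance of pair averages; proportional-bias regression undefined.")
    slope <- intercept <- r <- p <- NA_real_
  }

  ref_mean <- switch(reference,
    series_b = mean(b_vals),
    mean_of_both = mean(avgs)
  )
  stats <- tibble(
    variable = variable %||% NA_character_,
    n = n,
    mean_diff = mean_diff,
    sd_diff = sd_diff,
    loa_lower = mean_diff - loa_multiplier * sd_diff,
    loa_upper = mean_diff + loa_multiplier * sd_diff,
    loa_half_width = loa_multiplier * sd_diff,
    slope = slope,
    intercept = intercept,
    r = r,
    p_value = p,
    mean_diff_pct = if (isTRUE(ref_mean != 0)) 100 * mean_diff / ref_mean else NA_real_
  )
  structure(
    list(
      stats = stats,
      data = tibble(a = a_vals, b = b_vals, diff = diffs, avg = avgs),
      reference = reference,
      loa_multiplier = loa_multiplier
    ),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  s <- x$stats
  cat("Bland-Altman agreement (n = ", s$n, ")\n", sep = "")
  cat(sprintf("  mean difference: %.4g (%.2f%% of reference)\n",
              s$mean_diff, s$mean_diff_pct))
  cat(sprintf("  limits of agreement (+/- %g SD): [%.4g, %.4g]\n",
              x$loa_multiplier, s$loa_lower, s$loa_upper))
  cat(sprintf("  difference-on-average: slope %.3g, r %.3g, p %.3g\n",
              s$slope, s$r, s$p_value))
  invisible(x)
}

#' Choose a parametric or non-parametric test family
#'
#' Applies a Shapiro-Wilk normality test to the paired differences; if
#' normality is rejected at `alpha` the non-parametric family (Wilcoxon
#' signed rank / Spearman) is selected, otherwise the parametric family
#' (paired t / Pearson). The rule is an explicit default and can be
#' overridden per variable wherever a `family` argument is accepted.
#'
#' @param differences Numeric vector of paired differences (n >= 3).
#' @param alpha Rejection level for the normality test.
#' @return `"parametric"` or `"nonparametric"`.
#' @export
choose_family <- function(differences, alpha = 0.05) {
  differences <- differences[!is.na(differences)]
  if (length(differences) < 3) abort("Need at least 3 differences.")
  if (sd(differences) == 0) {
    return("nonparametric")
  }
  p <- shapiro.test(differences)$p.value
  if (p < alpha) "nonparametric" else "parametric"
}

#' Paired location test (paired t or Wilcoxon signed rank)
#'
#' @param data Data frame with the two methods' columns.
#' @param a,b Columns (tidyselect) of the paired values.
#' @param family `"auto"` (Shapiro-Wilk rule, see [choose_family()]),
#'   `"t"`, or `"wilcoxon"`.
#' @param approx_threshold Number of non-zero differences above which the
#'   Wilcoxon test uses the normal approximation; below it the exact
#'   distribution is used when there are no ties. Zero differences are
#'   excluded and ties are mid-ranked, the signed-rank convention.
#' @return One-row tibble: `family`, `statistic`, `p_value`, `n`,
#'   `mean_diff`. If every difference is zero, `p_value` is 1 by convention.
#' @export
paired_location_test <- function(data, a, b,
                                 family = c("auto", "t", "wilcoxon"),
                                 approx_threshold = 25) {
  family <- arg_match(family)
  a_vals <- dplyr::pull(data, {{ a }})
  b_vals <- dplyr::pull(data, {{ b }})
  keep <- stats::complete.cases(a_vals, b_vals)
  diffs <- (a_vals - b_vals)[keep]
  n <- length(diffs)
  if (n < 3) abort("Paired tests need at least 3 complete pairs.")

  if (family == "auto") {
    family <- if (choose_family(diffs) == "parametric") "t" else "wilcoxon"
  }
  if (all(diffs == 0)) {
    inform("All paired differences are zero; p = 1 by convention.")
    return(tibble(family = family, statistic = NA_real_, p_value = 1,
                  n = n, mean_diff = 0))
  }
  if (family == "t") {
    if (sd(diffs) == 0) {
      # constant non-zero shift: the t statistic degenerates
      inform("Constant non-zero differences; t statistic is infinite.")
      return(tibble(family = "t", statistic = sign(mean(diffs)) * Inf,
                    p_value = 0, n = n, mean_diff = mean(diffs)))
    }
    ht <- t.test(a_vals[keep], b_vals[keep], paired = TRUE)
    tibble(family = "t", statistic = unname(ht$statistic),
           p_value = ht$p.value, n = n, mean_diff = mean(diffs))
  } else {
    nz <- diffs[diffs != 0]
    if (length(nz) < 5) {
      warn("Fewer than 5 non-zero differences; Wilcoxon p is unreliable.")
    }
    exact <- length(nz) < approx_threshold && !any(duplicated(abs(nz)))
    ht <- suppressWarnings(
      wilcox.test(a_vals[keep], b_vals[keep], paired = TRUE, exact = exact,
                  correct = !exact)
    )
    tibble(family = "wilcoxon", statistic = unname(ht$statistic),
           p_value = ht$p.value, n = n, mean_diff = mean(diffs))
  }
}

#' Paired correlation (Pearson or Spearman)
#'
#' @inheritParams paired_location_test
#' @param family `"auto"` (Shapiro-Wilk on the differences), `"pearson"`,
#'   or `"spearman"` (Pearson on mid-ranks).
#' @return One-row tibble: `family`, `r`, `p_value`, `n`. Zero variance in
#'   either member yields `NA` with a warning.
#' @export
paired_correlation <- function(data, a, b,
                               family = c("auto", "pearson", "spearman")) {
  family <- arg_match(family)
  a_vals <- dplyr::pull(data, {{ a }})
  b_vals <- dplyr::pull(data, {{ b }})
  keep <- stats::complete.cases(a_vals, b_vals)
  a_vals <- a_vals[keep]
  b_vals <- b_vals[keep]
  n <- length(a_vals)
  if (n < 3) abort("Paired correlation needs at least 3 complete pairs.")
  if (family == "auto") {
    family <- if (choose_family(a_vals - b_vals) == "parametric") {
      "pearson"
    } else {
      "spearman"
    }
  }
  if (sd(a_vals) == 0 || sd(b_vals) == 0) {
    warn("Zero variance in one series; correlation undefined.")
    return(tibble(family = family, r = NA_real_, p_value = NA_real_, n = n))
  }
  ct <- suppressWarnings(
    cor.test(a_vals, b_vals, method = family,
             exact = if (family == "spearman") FALSE else NULL)
  )
  tibble(family = family, r = unname(ct$estimate), p_value = ct$p.value,
         n = n)
}

#' Validation summary table across variables
#'
#' Reproduces the standard method-comparison table: per variable, mean (SD)
#' under each method, a paired location test, a correlation, and the
#' Bland-Altman agreement statistics. The test/correlation family is chosen
#' per variable by the Shapiro-Wilk rule unless overridden.
#'
#' @param a_data,b_data Participant-level tibbles for the two methods, each
#'   with `participant_id` and the `variables` columns (e.g. two methods'
#'   [participant_means()] outputs). Participants present in only one table
#'   are dropped with a message.
#' @param variables Character vector of variable columns to compare.
#' @param family `"auto"`, `"parametric"` or `"nonparametric"`, recycled
#'   over variables; or a named character vector of per-variable overrides.
#' @param reference Passed to [bland_altman()].
#' @param p_adjust Multiple-testing correction for the location-test p
#'   values (any [stats::p.adjust()] method); `"none"` by default.
#' @return A tibble of class `method_comparison`, one row per variable:
#'   means/SDs, `test_family`, `p_diff`, `cor_family`, `r`, `p_cor`, and the
#'   Bland-Altman columns. The per-variable `bland_altman` objects are
#'   attached as attribute `"ba"`.
#' @export
compare_methods <- function(a_data, b_data, variables,
                            family = "auto",
                            reference = c("series_b", "mean_of_both"),
                            p_adjust = "none") {
  reference <- arg_match(reference)
  stopifnot(all(variables %in% names(a_data)),
            all(variables %in% names(b_data)))
  matched <- inner_join(
    select(a_data, "participant_id", all_of(variables)),
    select(b_data, "participant_id", all_of(variables)),
    by = "participant_id", suffix = c("_a", "_b")
  )
  n_dropped <- n_distinct(a_data$participant_id) +
    n_distinct(b_data$participant_id) - 2 * nrow(matched)
  if (n_dropped > 0) {
    inform(paste0(n_dropped, " unmatched participant record(s) dropped."))
  }
  if (length(family) > 1 && is.null(names(family))) {
    abort("Per-variable `family` overrides must be named.")
  }

  ba_objects <- list()
  rows <- purrr::map_dfr(variables, function(v) {
    av <- matched[[paste0(v, "_a")]]
    bv <- matched[[paste0(v, "_b")]]
    fam <- if (is.null(names(family))) family else (family[v] %||% "auto")
    fam <- unname(fam)
    keep <- stats::complete.cases(av, bv)
    if (fam == "auto") {
      fam <- choose_family(av[keep] - bv[keep])
    }
    pair <- tibble(a = av, b = bv)
    test <- paired_location_test(pair, a, b,
                                 family = if (fam == "parametric") "t" else "wilcoxon")
    corr <- paired_correlation(pair, a, b,
                               family = if (fam == "parametric") "pearson" else "spearman")
    ba <- bland_altman(pair, a, b, reference = reference, variable = v)
    ba_objects[[v]] <<- ba
    tibble(
      variable = v,
      n = sum(keep),
      mean_a = mean(av[keep]), sd_a = sd(av[keep]),
      mean_b = mean(bv[keep]), sd_b = sd(bv[keep]),
      test_family = test$family, statistic = test$statistic,
      p_diff = test$p_value,
      cor_family = corr$family, r = corr$r, p_cor = corr$p_value,
      mean_diff = ba$stats$mean_diff, sd_diff = ba$stats$sd_diff,
      loa_lower = ba$stats$loa_lower, loa_upper = ba$stats$loa_upper,
      ba_slope = ba$stats$slope, ba_r = ba$stats$r,
      ba_p = ba$stats$p_value
    )
  })
  rows$p_diff_adj <- stats::p.adjust(rows$p_diff, method = p_adjust)
  structure(rows, ba = ba_objects,
            class = c("method_comparison", class(rows)))
}
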