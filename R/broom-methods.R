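#' Tidy a Bland-Altman analysis
#'
#' @param x A [bland_altman()] object.
#' @param ... Unused.
#' @return A tibble with one row per statistic (`term`, `estimate`).
#' @method tidy bland_altman
#' @export
tidy.bland_altman <- function(x, ...) {
  s <- select(x$stats, -any_of("variable"))
  tibble(term = names(s), estimate = as.numeric(s[1, ]))
}

#' One-row summary of a Bland-Altman analysis
#'
#' @inheritParams tidy.bland_altman
#' @return The one-row `stats` tibble.
#' @method glance bland_altman
#' @export
glance.bland_altman <- function(x, ...) x$stats

#' Per-pair data from a Bland-Altman analysis
#'
#' @inheritParams tidy.bland_altman
#' @return The per-pair tibble (`a`, `b`, `diff`, `avg`) with a
#'   `within_loa` indicator.
#' @method augment bland_altman
#' @export
augment.bland_altman <- function(x, ...) {
  x$data %>%
    mutate(within_loa = .data$diff >= x$stats$loa_lower &
             .data$diff <= x$stats$loa_upper)
}

#' Bland-Altman plot
#'
#' Difference-vs-average scatter with the mean difference (solid), limits
#' of agreement (dashed) and, optionally, the difference-on-average
#' regression line used to judge proportional bias.
#'
#' @param object A [bland_altman()] object.
#' @param show_regression Draw the proportional-bias regression line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bland_altman
#' @export
autoplot.bland_altman <- function(object, show_regression = TRUE, ...) {
  s <- object$stats
  p <- ggplot2::ggplot(object$data, ggplot2::aes(x = .data$avg, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_hline(yintercept = s$mean_diff, linewidth = 0.6) +
    ggplot2::geom_hline(yintercept = c(s$loa_lower, s$loa_upper),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "Average of the two methods",
      y = "Difference (A - B)",
      title = if (!is.na(s$variable)) s$variable else NULL,
      subtitle = sprintf("mean diff %.3g, LoA [%.3g, %.3g]",
                         s$mean_diff, s$loa_lower, s$loa_upper)
    ) +
    ggplot2::theme_minimal()
  if (show_regression && !is.na(s$slope)) {
    p <- p + ggplot2::geom_abline(slope = s$slope, intercept = s$intercept,
                                  colour = "steelblue")
  }
  p
}

#' Isotope washout plot
#'
#' Log-scale excess enrichment against time since dose with the fitted
#' elimination lines, per participant and isotope.
#'
#' @param object An [fit_elimination()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot elimination_fit
#' @export
autoplot.elimination_fit <- function(object, ...) {
  points <- attr(object, "points")
  fits <- as_tibble(object) %>%
    mutate(intercept_log = log(.data$zero_time_excess), slope = -.data$k)
  ggplot2::ggplot(points,
                  ggplot2::aes(x = .data$time_days, y = log(.data$excess),
                               colour = .data$isotope)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(
      data = fits,
      ggplot2::aes(slope = .data$slope, intercept = .data$intercept_log,
                   colour = .data$isotope)
    ) +
    ggplot2::facet_wrap(~participant_id) +
    ggplot2::labs(x = "Days since dose", y = "ln(excess enrichment)") +
    ggplot2::theme_minimal()
}

#' Tidy a method-comparison table
#'
#' @param x A [compare_methods()] result.
#' @param ... Unused.
#' @return The underlying tibble (already one row per variable).
#' @method tidy method_comparison
#' @export
tidy.method_comparison <- function(x, ...) as_tibble(x)
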