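#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy a linear-quadratic fit
#'
#' @param x an `lq_fit`.
#' @param conf.level confidence level for the Wald intervals (log-survival
#'   scale OLS covariance).
#' @param ... unused.
#' @return One row per parameter: `term`, `estimate`, `std.error`,
#'   `conf.low`, `conf.high`.
#' @method tidy lq_fit
#' @export
tidy.lq_fit <- function(x, conf.level = 0.95, ...) {
  se <- sqrt(diag(x$vcov))
  tcrit <- qt(1 - (1 - conf.level) / 2, x$df)
  tibble::tibble(
    term = c("alpha", "beta"),
    estimate = c(x$alpha, x$beta),
    std.error = se,
    conf.low = c(x$alpha, x$beta) - tcrit * se,
    conf.high = c(x$alpha, x$beta) + tcrit * se
  )
}

#' @rdname tidy.lq_fit
#' @method glance lq_fit
#' @export
glance.lq_fit <- function(x, ...) {
  tibble::tibble(rss = x$rss, df = x$df, n_points = x$n_points,
                 boundary = x$boundary)
}

#' Tidy a shared-versus-separate curve comparison
#'
#' @param x a `curve_comparison`.
#' @param ... unused.
#' @return A one-row tibble with the F statistic, degrees of freedom,
#'   p-value and the shared-curve decision.
#' @method tidy curve_comparison
#' @export
tidy.curve_comparison <- function(x, ...) {
  tibble::tibble(F = x$F, df_num = x$df_num, df_den = x$df_den, p = x$p,
                 shared_curve = x$shared_curve, model = x$model)
}

#' @rdname tidy.curve_comparison
#' @method glance curve_comparison
#' @export
glance.curve_comparison <- function(x, ...) {
  tibble::tibble(rss_pooled = x$rss_pooled, rss_separate = x$rss_separate,
                 n_groups = x$n_groups, n_points = x$n_points, p = x$p)
}

#' Tidy ANOVA/Tukey results
#'
#' @param x an `anova_tukey`.
#' @param ... unused.
#' @return `tidy()` returns the per-pair Tukey table; `glance()` the
#'   one-row ANOVA summary.
#' @method tidy anova_tukey
#' @export
tidy.anova_tukey <- function(x, ...) x$tukey

#' @rdname tidy.anova_tukey
#' @method glance anova_tukey
#' @export
glance.anova_tukey <- function(x, ...) x$anova

#' Tidy per-temperature plating-efficiency regressions
#'
#' @param x a `pe_linear_fit`.
#' @param ... unused.
#' @return The per-temperature slope table; the pairwise shared-line tests
#'   remain available as `x$pairwise`.
#' @method tidy pe_linear_fit
#' @export
tidy.pe_linear_fit <- function(x, ...) x$fits

#' Plot a linear-quadratic survival fit
#'
#' @param object an `lq_fit`.
#' @param ... unused.
#' @return A ggplot: surviving-fraction points and the fitted curve on a
#'   log survival axis.
#' @method autoplot lq_fit
#' @export
autoplot.lq_fit <- function(object, ...) {
  grid <- tibble::tibble(
    dose_Gy = seq(0, max(object$data$dose_Gy), length.out = 100)
  )
  grid$sf <- predict(object, grid$dose_Gy)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$dose_Gy, y = .data$sf)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Radiation dose (Gy)", y = "Surviving fraction",
                  title = sprintf("LQ fit: alpha = %.3g /Gy, beta = %.3g /Gy^2",
                                  object$alpha, object$beta)) +
    ggplot2::theme_minimal()
}

#' Survival curves for several thermal doses
#'
#' Points are per-plate surviving fractions; lines are per-group
#' linear-quadratic fits.
#'
#' @param sf tibble from [surviving_fraction()].
#' @param group column distinguishing the curves (e.g. `duration_min`).
#' @return A ggplot.
#' @export
plot_survival_curves <- function(sf, group = "duration_min") {
  gvals <- sort(unique(sf[[group]]))
  curves <- purrr::map_dfr(gvals, function(g) {
    d <- sf[sf[[group]] == g, ]
    fit <- fit_lq(d)
    tibble::tibble(
      !!group := g,
      dose_Gy = seq(0, max(d$dose_Gy), length.out = 100)
    ) |>
      dplyr::mutate(sf = predict(fit, .data$dose_Gy))
  })
  ggplot2::ggplot(sf, ggplot2::aes(x = .data$dose_Gy, y = .data$sf,
                                   colour = factor(.data[[group]]))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_line(data = curves) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Radiation dose (Gy)", y = "Surviving fraction",
                  colour = group) +
    ggplot2::theme_minimal()
}

#' Focus-morphology scatter (count versus mean integrated density)
#'
#' The per-nucleus plane in which the three focus categories separate;
#' points are nuclei, coloured by category when present.
#'
#' @param profiles tibble from [profile_nuclei()] or
#'   [classify_category()].
#' @return A ggplot.
#' @export
plot_focus_scatter <- function(profiles) {
  d <- dplyr::filter(profiles, .data$focus_count > 0,
                     is.finite(.data$mean_integrated_density))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$focus_count,
                                       y = .data$mean_integrated_density))
  if ("category" %in% names(d)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = factor(.data$category)),
                                 alpha = 0.7) +
      ggplot2::labs(colour = "Category")
  } else {
    p <- p + ggplot2::geom_point(alpha = 0.7)
  }
  p +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "RAD51 foci per nucleus",
                  y = "Mean integrated density per focus (um^2 a.u.)") +
    ggplot2::theme_minimal()
}

#' Relative protein levels across thermal doses
#'
#' Mean +/- SEM of the normalized band levels per condition.
#'
#' @param levels tibble from [normalize_levels()].
#' @return A ggplot.
#' @export
plot_blot_levels <- function(levels) {
  summ <- levels |>
    dplyr::group_by(.data$temperature_C, .data$duration_min) |>
    dplyr::summarise(mean = mean(.data$level),
                     sem = sd(.data$level) / sqrt(dplyr::n()),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$duration_min, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$sem,
                                        ymax = .data$mean + .data$sem),
                           width = 5) +
    ggplot2::facet_wrap(~temperature_C, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "Treatment duration (min)",
                  y = "Level (% of 37 degC control)") +
    ggplot2::theme_minimal()
}
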