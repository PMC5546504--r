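#' Quantify a band from a lane densitometry profile
#'
#' Integrates the lane intensity profile over a peak window after
#' subtracting a straight baseline joining the profile values at the window
#' endpoints — the convention of profile-based gel quantification. The
#' integral is evaluated by the trapezoidal rule on the profile samples
#' inside the window plus interpolated endpoint values; a negative net area
#' is floored at 0 with a warning.
#'
#' @param profile tibble with columns `position` (strictly increasing) and
#'   `intensity` (non-negative).
#' @param window numeric length-2 vector `c(lo, hi)` within the profile
#'   extent.
#' @return A single number: the baseline-subtracted band signal.
#' @examples
#' prof <- tibble::tibble(position = 0:50,
#'                        intensity = ifelse(0:50 %in% 20:30, 5, 0))
#' quantify_band(prof, c(15, 35))
#' @export
quantify_band <- function(profile, window) {
  stopifnot(
    is.data.frame(profile),
    all(c("position", "intensity") %in% names(profile)),
    all(diff(profile$position) > 0),
    all(profile$intensity >= 0)
  )
  if (length(window) != 2L || window[1] >= window[2]) {
    abort("`window` must be c(lo, hi) with lo < hi")
  }
  if (window[1] < min(profile$position) || window[2] > max(profile$position)) {
    abort("`window` extends beyond the profile extent")
  }
  inside <- profile$position > window[1] & profile$position < window[2]
  y_lo <- approx(profile$position, profile$intensity, xout = window[1])$y
  y_hi <- approx(profile$position, profile$intensity, xout = window[2])$y
  xs <- c(window[1], profile$position[inside], window[2])
  ys <- c(y_lo, profile$intensity[inside], y_hi)
  # straight baseline between the window endpoints
  base <- y_lo + (y_hi - y_lo) * (xs - window[1]) / (window[2] - window[1])
  net <- ys - base
  n <- length(xs)
  signal <- sum(diff(xs) * (net[-1] + net[-n]) / 2)
  if (signal < 0) {
    warn(sprintf("negative net band area (%.4g) floored at 0", signal))
    signal <- 0
  }
  signal
}

#' Normalize band signals to loading control and 37 degC reference
#'
#' Each band is first divided by its lane's loading-control signal (this
#' corrects unequal loading), then expressed as a percentage of the
#' control-normalized signal of the 37 degC reference (the 0-minute arm)
#' of the same blot, cell line and lysate fraction.
#'
#' @param bands tibble with columns `target_signal`, `control_signal` and
#'   the condition labels `temperature_C`, `duration_min`; optional grouping
#'   columns `experiment`, `cell_line`, `fraction` are respected when
#'   present.
#' @return The input with `ratio` (target / control) and `level` (percent of
#'   the 37 degC reference) appended.
#' @export
normalize_levels <- function(bands) {
  needed <- c("temperature_C", "duration_min", "target_signal", "control_signal")
  stopifnot(all(needed %in% names(bands)))
  if (any(bands$control_signal <= 0)) {
    abort("loading-control signal must be positive in every lane")
  }
  grp <- intersect(c("experiment", "cell_line", "temperature_C", "fraction"),
                   names(bands))
  bands <- dplyr::mutate(bands, ratio = .data$target_signal / .data$control_signal)
  ref <- bands |>
    dplyr::filter(.data$duration_min == 0) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(grp))) |>
    dplyr::summarise(ratio_ref = mean(.data$ratio), .groups = "drop")
  if (nrow(ref) == 0L) abort("no 37 degC reference lanes (duration_min == 0)")
  if (any(ref$ratio_ref <= 0)) abort("37 degC reference band signal is zero")
  out <- dplyr::left_join(bands, ref, by = grp)
  if (anyNA(out$ratio_ref)) abort("some blots lack a 37 degC reference lane")
  dplyr::mutate(out, level = 100 * .data$ratio / .data$ratio_ref)
}

#' One-way ANOVA with Tukey HSD multiple comparisons
#'
#' Tests whether mean levels differ across conditions (one-way ANOVA) and,
#' if so, which pairs differ (Tukey's honestly-significant-difference test,
#' Tukey-Kramer for unbalanced groups). Groups with fewer than two
#' replicates carry no within-group variance and are excluded with a
#' warning.
#'
#' @param data tibble of per-replicate values.
#' @param value,group column names of the response and the grouping factor.
#' @param alpha_level significance level for flagging pairs.
#' @return An object of class `anova_tukey` with elements `anova` (tibble:
#'   `df_between`, `df_within`, `F`, `p`) and `tukey` (tibble: `contrast`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `significant`).
#' @export
anova_tukey <- function(data, value, group, alpha_level = 0.05) {
  stopifnot(all(c(value, group) %in% names(data)))
  d <- tibble::tibble(y = data[[value]], g = as.character(data[[group]]))
  sizes <- table(d$g)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warn(sprintf("excluding groups with < 2 replicates: %s",
                 paste(small, collapse = ", ")))
    d <- dplyr::filter(d, !.data$g %in% small)
  }
  if (dplyr::n_distinct(d$g) < 2L) abort("need at least 2 groups with n >= 2")
  d$g <- factor(d$g)
  fit <- aov(y ~ g, data = d)
  an <- summary(fit)[[1]]
  hsd <- TukeyHSD(fit, conf.level = 1 - alpha_level)$g
  tukey <- tibble::tibble(
    contrast = rownames(hsd),
    diff = unname(hsd[, "diff"]), lwr = unname(hsd[, "lwr"]),
    upr = unname(hsd[, "upr"]),
    p_adj = unname(hsd[, "p adj"]),
    significant = unname(hsd[, "p adj"] < alpha_level)
  )
  structure(
    list(
      anova = tibble::tibble(
        df_between = an$Df[1], df_within = an$Df[2],
        F = an$`F value`[1], p = an$`Pr(>F)`[1]
      ),
      tukey = tukey,
      alpha_level = alpha_level
    ),
    class = "anova_tukey"
  )
}

#' @export
print.anova_tukey <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$anova$df_between, x$anova$df_within, x$anova$F, x$anova$p))
  cat("Tukey HSD:\n")
  print(x$tukey)
  invisible(x)
}

#' Compare protein time courses across lysate fractions
#'
#' Given relative protein levels over treatment time in the whole extract,
#' supernatant and pellet fractions, decides whether the three time courses
#' follow one shared curve or separate curves (quadratic-in-time model via
#' [compare_curves()]), and runs pairwise Welch t-tests between fractions at
#' each shared time point.
#'
#' @param levels tibble with columns `fraction`, `duration_min`, `level`
#'   (percent of control) and replicates as rows.
#' @param fractions the fraction labels expected (all must be present).
#' @param alpha_level significance level.
#' @return A list of class `fractionation_result`: `comparison` (a
#'   `curve_comparison`) and `t_tests` (tibble of per-time pairwise tests).
#' @export
fractionation_analysis <- function(levels,
                                   fractions = c("whole", "supernatant", "pellet"),
                                   alpha_level = 0.05) {
  stopifnot(all(c("fraction", "duration_min", "level") %in% names(levels)))
  missing_fr <- setdiff(fractions, unique(levels$fraction))
  if (length(missing_fr)) {
    abort(sprintf("missing fraction(s): %s", paste(missing_fr, collapse = ", ")))
  }
  levels <- dplyr::filter(levels, .data$fraction %in% fractions)
  shared_t <- levels |>
    dplyr::group_by(.data$duration_min) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$fraction), .groups = "drop") |>
    dplyr::filter(.data$k == length(fractions)) |>
    dplyr::pull(.data$duration_min)
  if (length(shared_t) < 3L) {
    abort("insufficient df: fractions must share at least 3 time points")
  }
  levels <- dplyr::filter(levels, .data$duration_min %in% shared_t)
  cmp <- compare_curves(levels, group = "fraction", x = "duration_min",
                        y = "level", model = "quadratic",
                        alpha_level = alpha_level)
  pairs <- utils::combn(fractions, 2L, simplify = FALSE)
  tt <- tidyr::crossing(duration_min = shared_t, pair = pairs) |>
    purrr::pmap_dfr(function(duration_min, pair) {
      a <- levels$level[levels$duration_min == duration_min &
                          levels$fraction == pair[1]]
      b <- levels$level[levels$duration_min == duration_min &
                          levels$fraction == pair[2]]
      if (length(a) < 2L || length(b) < 2L) return(NULL)
      dplyr::bind_cols(
        tibble::tibble(duration_min = duration_min,
                       fraction_a = pair[1], fraction_b = pair[2]),
        t_test_groups(a, b)
      )
    })
  structure(list(comparison = cmp, t_tests = tt, alpha_level = alpha_level),
            class = "fractionation_result")
}

#' @export
print.fractionation_result <- function(x, ...) {
  print(x$comparison)
  cat("\nPer-time pairwise t-tests:\n")
  print(x$t_tests)
  invisible(x)
}
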