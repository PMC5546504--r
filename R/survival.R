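#' Plating efficiency, normalized to the 37 degC control
#'
#' Computes the plating efficiency PE = colonies / seeded for every 0 Gy
#' plate and expresses it as a percentage of the 37 degC control (the
#' 0-minute arm of the same cell line and experiment).
#'
#' @param obs tibble of survival observations with columns `cell_line`,
#'   `temperature_C`, `duration_min`, `dose_Gy`, `seeded`, `colonies`.
#' @return A tibble of 0 Gy plates with `pe` (fraction) and `pe_norm`
#'   (percent of the 37 degC reference of the same cell line and
#'   temperature experiment).
#' @export
plating_efficiency <- function(obs) {
  stopifnot(all(c("cell_line", "temperature_C", "duration_min",
                  "dose_Gy", "seeded", "colonies") %in% names(obs)))
  pe0 <- obs |>
    dplyr::filter(.data$dose_Gy == 0) |>
    dplyr::mutate(pe = .data$colonies / .data$seeded)
  ref <- pe0 |>
    dplyr::filter(.data$duration_min == 0 | .data$temperature_C == 37) |>
    dplyr::group_by(.data$cell_line, .data$temperature_C) |>
    dplyr::summarise(pe_ref = mean(.data$pe), .groups = "drop")
  if (nrow(ref) == 0L) {
    abort("no 37 degC reference plates (duration_min == 0) found")
  }
  if (any(ref$pe_ref == 0)) {
    abort("reference plating efficiency at 37 degC is zero")
  }
  out <- dplyr::left_join(pe0, ref, by = c("cell_line", "temperature_C"))
  if (anyNA(out$pe_ref)) {
    abort("some conditions lack a 37 degC reference plate")
  }
  dplyr::mutate(out, pe_norm = 100 * .data$pe / .data$pe_ref)
}

#' Linear regression of normalized plating efficiency on treatment duration
#'
#' Fits, per temperature, an ordinary least-squares line through normalized
#' plating efficiency (percent of control) versus treatment duration, and
#' tests every pair of temperatures for a common line with the
#' extra-sum-of-squares F-test (a significant F means the two temperatures
#' need separate regression lines).
#'
#' @param pe tibble from [plating_efficiency()] (columns `temperature_C`,
#'   `duration_min`, `pe_norm`); cell lines are pooled.
#' @param alpha_level significance level for the pairwise line comparisons.
#' @return An object of class `pe_linear_fit` with elements `fits` (per
#'   temperature: slope, standard error, intercept) and `pairwise`
#'   (per temperature pair: F, degrees of freedom, p, `shared_curve`).
#' @export
fit_pe_linear <- function(pe, alpha_level = 0.05) {
  stopifnot(all(c("temperature_C", "duration_min", "pe_norm") %in% names(pe)))
  n_dur <- pe |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::summarise(k = dplyr::n_distinct(.data$duration_min), .groups = "drop")
  if (any(n_dur$k < 3L)) {
    abort("each temperature needs at least 3 distinct durations for a linear fit")
  }
  fits <- pe |>
    dplyr::group_by(.data$temperature_C) |>
    dplyr::group_modify(function(d, key) {
      fit <- lm(pe_norm ~ duration_min, data = d)
      s <- summary(fit)$coefficients
      tibble::tibble(
        intercept = s["(Intercept)", "Estimate"],
        slope = s["duration_min", "Estimate"],
        slope_se = s["duration_min", "Std. Error"],
        n = nrow(d)
      )
    }) |>
    dplyr::ungroup()

  temps <- sort(unique(pe$temperature_C))
  pairs <- utils::combn(temps, 2L, simplify = FALSE)
  pairwise <- purrr::map_dfr(pairs, function(pr) {
    sub <- dplyr::filter(pe, .data$temperature_C %in% pr)
    cmp <- compare_curves(sub,
                          group = "temperature_C",
                          x = "duration_min", y = "pe_norm",
                          model = "linear", alpha_level = alpha_level)
    tibble::tibble(
      temperature_A = pr[1], temperature_B = pr[2],
      F = cmp$F, df_num = cmp$df_num, df_den = cmp$df_den,
      p = cmp$p, shared_curve = cmp$shared_curve
    )
  })
  structure(list(fits = fits, pairwise = pairwise,
                 alpha_level = alpha_level),
            class = "pe_linear_fit")
}

#' @export
print.pe_linear_fit <- function(x, ...) {
  cat("Linear plating-efficiency regression (percent of control vs minutes)\n")
  print(x$fits)
  cat(sprintf("\nPairwise shared-line tests at alpha = %g:\n", x$alpha_level))
  print(x$pairwise)
  invisible(x)
}

#' Surviving fraction, normalized to 0 Gy within each thermal dose
#'
#' SF(D) = PE(D) / PE(0 Gy), computed per plate with the 0 Gy plating
#' efficiency averaged over its replicates within the same cell line and
#' thermal dose, so that the mean surviving fraction at 0 Gy is exactly 1.
#'
#' @param obs tibble of survival observations (see [plating_efficiency()]).
#' @return The input restricted to usable conditions, with columns `pe` and
#'   `sf` appended.
#' @export
surviving_fraction <- function(obs) {
  stopifnot(all(c("cell_line", "temperature_C", "duration_min",
                  "dose_Gy", "seeded", "colonies") %in% names(obs)))
  obs <- dplyr::mutate(obs, pe = .data$colonies / .data$seeded)
  ref <- obs |>
    dplyr::filter(.data$dose_Gy == 0) |>
    dplyr::group_by(.data$cell_line, .data$temperature_C, .data$duration_min) |>
    dplyr::summarise(pe0 = mean(.data$pe), .groups = "drop")
  if (nrow(ref) == 0L) abort("no 0 Gy plates found")
  if (any(ref$pe0 == 0)) abort("plating efficiency at 0 Gy is zero for some condition")
  out <- dplyr::inner_join(obs, ref,
                           by = c("cell_line", "temperature_C", "duration_min"))
  dplyr::mutate(out, sf = .data$pe / .data$pe0)
}

# Constrained least squares for the log-survival design
#   y = [free columns] + alpha * (-D) + beta * (-D^2),  alpha, beta >= 0.
# `free` holds always-unconstrained columns (per-group normalization
# intercepts); with only two constrained parameters the non-negative
# solution is found exactly by enumerating the active sets.
lq_solve <- function(D, y, free = NULL, weights = NULL) {
  n <- length(D)
  w <- if (is.null(weights)) rep(1, n) else weights
  sw <- sqrt(w)
  nf <- if (is.null(free)) 0L else ncol(free)
  X <- cbind(free, `-D` = -D, `-D2` = -D^2)
  rss_of <- function(theta) sum(w * (y - X %*% theta)^2)
  fit_ls <- function(cols) {
    th <- rep(0, ncol(X))
    keep <- c(seq_len(nf), nf + cols)
    if (length(keep)) {
      th[keep] <- qr.coef(qr(sw * X[, keep, drop = FALSE]), sw * y)
    }
    th
  }
  cands <- list(fit_ls(1:2), fit_ls(1L), fit_ls(2L), fit_ls(integer(0)))
  feas <- purrr::keep(cands, ~ all(.x[nf + 1:2] >= 0))
  rss <- purrr::map_dbl(feas, rss_of)
  best <- feas[[which.min(rss)]]
  list(theta = best, rss = min(rss), X = X, w = w,
       boundary = !all(cands[[1]][nf + 1:2] >= -1e-12))
}

#' Fit the linear-quadratic survival model
#'
#' Least-squares fit of `log(SF) = c - (alpha * D + beta * D^2)` with the
#' radiobiological constraint `alpha, beta >= 0` (set `constrain = FALSE`
#' for an unconstrained diagnostic fit). The free constant `c` is a
#' log-scale normalization intercept: surviving fractions are normalized to
#' an *estimated* 0 Gy plating efficiency, and treating that normalization
#' as exact would make every point in a dataset share its error, giving
#' overconfident intervals and miscalibrated curve comparisons. On exactly
#' normalized (noise-free) data `c` is 0 and alpha, beta are recovered
#' exactly; `intercept = FALSE` forces the curve through SF(0) = 1.
#' Replicate plates enter as individual points. Points with `SF <= 0`
#' cannot be log-transformed and are dropped with a warning.
#'
#' @param data tibble with dose and surviving-fraction columns.
#' @param dose,sf names of the dose (Gy) and surviving-fraction columns.
#' @param weights optional numeric vector of least-squares weights.
#' @param constrain enforce `alpha, beta >= 0` (default TRUE).
#' @param intercept estimate the free normalization constant (default TRUE).
#' @return An object of class `lq_fit`: fields `alpha` (per Gy), `beta`
#'   (per Gy squared), `log_norm` (the fitted `c`), `rss` and `df` on the
#'   log-survival scale, `n_points`, `vcov`, and `boundary` (TRUE when a
#'   constraint is active).
#' @examples
#' d <- tibble::tibble(dose_Gy = c(0, 2, 4, 6),
#'                     sf = exp(-(0.5 * dose_Gy + 0.05 * dose_Gy^2)))
#' fit_lq(d)
#' @export
fit_lq <- function(data, dose = "dose_Gy", sf = "sf", weights = NULL,
                   constrain = TRUE, intercept = TRUE) {
  D <- data[[dose]]
  S <- data[[sf]]
  stopifnot(is.numeric(D), is.numeric(S))
  bad <- !is.finite(S) | S <= 0 | !is.finite(D)
  if (any(bad)) {
    warn(sprintf("dropping %d points with SF <= 0 (log undefined)", sum(bad)))
    D <- D[!bad]; S <- S[!bad]
    if (!is.null(weights)) weights <- weights[!bad]
  }
  if (length(unique(D)) < 3L) {
    abort("fewer than 3 usable distinct doses for the linear-quadratic fit")
  }
  y <- log(S)
  n <- length(D)
  free <- if (intercept) matrix(1, n, 1, dimnames = list(NULL, "c")) else NULL
  nf <- if (intercept) 1L else 0L
  if (constrain) {
    sol <- lq_solve(D, y, free, weights)
    theta <- sol$theta
    rss <- sol$rss
    boundary <- sol$boundary
  } else {
    X <- cbind(free, -D, -D^2)
    w <- if (is.null(weights)) rep(1, n) else weights
    theta <- as.vector(qr.coef(qr(sqrt(w) * X), sqrt(w) * y))
    rss <- sum(w * (y - X %*% theta)^2)
    boundary <- FALSE
  }
  df <- n - 2L - nf
  X <- cbind(free, -D, -D^2)
  w <- if (is.null(weights)) rep(1, n) else weights
  XtX <- crossprod(sqrt(w) * X)
  vc_full <- if (df >= 1L) (rss / df) * solve(XtX) else
    matrix(NA_real_, ncol(X), ncol(X))
  vc <- vc_full[nf + 1:2, nf + 1:2, drop = FALSE]
  dimnames(vc) <- list(c("alpha", "beta"), c("alpha", "beta"))
  structure(
    list(alpha = theta[nf + 1], beta = theta[nf + 2],
         log_norm = if (intercept) theta[1] else 0,
         rss = rss, df = df,
         n_points = n, vcov = vc, boundary = boundary,
         constrain = constrain, intercept = intercept,
         data = tibble::tibble(dose_Gy = D, sf = S)),
    class = "lq_fit"
  )
}

#' @export
print.lq_fit <- function(x, ...) {
  cat(sprintf(
    "Linear-quadratic fit: alpha = %.4g /Gy, beta = %.4g /Gy^2 (n = %d, rss = %.4g, df = %d)%s\n",
    x$alpha, x$beta, x$n_points, x$rss, x$df,
    if (x$boundary) " [constraint active]" else ""))
  invisible(x)
}

#' Predicted surviving fraction from a linear-quadratic fit
#'
#' @param object an `lq_fit`.
#' @param dose_Gy doses at which to predict.
#' @param ... unused.
#' @return Numeric vector of predicted surviving fractions.
#' @export
predict.lq_fit <- function(object, dose_Gy, ...) {
  exp(object$log_norm - (object$alpha * dose_Gy + object$beta * dose_Gy^2))
}

# Residual sum of squares of pooled / per-group fits for compare_curves.
# For the pooled LQ model each group keeps its own normalization intercept
# (the curve parameters alpha, beta are what is shared and tested).
curve_rss <- function(data, x, y, model, constrain, group = NULL) {
  xs <- data[[x]]; ys <- data[[y]]
  switch(model,
    lq = {
      if (is.null(group)) {
        fit <- fit_lq(tibble::tibble(dose_Gy = xs, sf = ys),
                      constrain = constrain)
        list(rss = fit$rss, n = fit$n_points, p = 3L)
      } else {
        bad <- !is.finite(ys) | ys <= 0
        if (any(bad)) {
          warn(sprintf("dropping %d points with SF <= 0 (log undefined)",
                       sum(bad)))
          xs <- xs[!bad]; ys <- ys[!bad]
        }
        g <- factor(data[[group]][if (any(bad)) !bad else TRUE])
        dummies <- stats::model.matrix(~ g - 1)
        if (constrain) {
          sol <- lq_solve(xs, log(ys), free = dummies)
          rss <- sol$rss
        } else {
          X <- cbind(dummies, -xs, -xs^2)
          th <- qr.coef(qr(X), log(ys))
          rss <- sum((log(ys) - X %*% th)^2)
        }
        list(rss = rss, n = length(xs), p = nlevels(g) + 2L)
      }
    },
    linear = {
      fit <- lm(ys ~ xs)
      list(rss = sum(fit$residuals^2), n = length(xs), p = 2L)
    },
    quadratic = {
      fit <- lm(ys ~ xs + I(xs^2))
      list(rss = sum(fit$residuals^2), n = length(xs), p = 3L)
    },
    abort(sprintf("unknown model '%s'", model))
  )
}

#' Shared-versus-separate curve comparison (extra-sum-of-squares F-test)
#'
#' Decides whether one pooled curve explains several groups of points or
#' whether each group needs its own curve, by the nested-model F-test:
#' `F = ((RSS_pooled - RSS_sep) / (df_pooled - df_sep)) / (RSS_sep / df_sep)`.
#' A small p-value rejects the shared curve. This is the decision rule used
#' both for survival curves across thermal doses (linear-quadratic model on
#' log surviving fraction) and for protein-level time courses (linear or
#' quadratic model on the raw response).
#'
#' @param data tibble of points from all groups.
#' @param group,x,y column names of the group label, predictor and response.
#' @param model `"lq"` (log-linear-quadratic survival, response must be a
#'   surviving fraction), `"linear"`, or `"quadratic"`.
#' @param alpha_level significance level for the shared-curve decision.
#' @param constrain passed to [fit_lq()] for the `"lq"` model.
#' @return An object of class `curve_comparison`: `F`, `df_num`, `df_den`,
#'   `p`, `shared_curve` (TRUE iff `p >= alpha_level`), plus the pooled and
#'   separate residual sums of squares.
#' @examples
#' d <- gen_colony_counts(survival_gen_config(
#'   design = tibble::tibble(temperature_C = c(40, 42), duration_min = c(60, 60)),
#'   seed = 7
#' ))
#' sf <- surviving_fraction(d)
#' compare_curves(sf, group = "temperature_C", x = "dose_Gy", y = "sf", model = "lq")
#' @export
compare_curves <- function(data, group, x, y,
                           model = c("lq", "linear", "quadratic"),
                           alpha_level = 0.05, constrain = TRUE) {
  model <- match.arg(model)
  g <- data[[group]]
  k <- dplyr::n_distinct(g)
  if (k < 2L) abort("need at least 2 groups to compare curves")
  pooled <- curve_rss(data, x, y, model, constrain,
                      group = if (model == "lq") group else NULL)
  parts <- lapply(split(data, g), curve_rss, x = x, y = y,
                  model = model, constrain = constrain)
  rss_sep <- sum(purrr::map_dbl(parts, "rss"))
  n <- pooled$n
  df_pooled <- n - pooled$p
  df_sep <- n - sum(purrr::map_dbl(parts, "p"))
  if (df_sep <= 0L) abort("insufficient data for comparison")
  Fstat <- max(0, ((pooled$rss - rss_sep) / (df_pooled - df_sep)) /
                 (rss_sep / df_sep))
  pval <- pf(Fstat, df_pooled - df_sep, df_sep, lower.tail = FALSE)
  structure(
    list(F = Fstat, df_num = df_pooled - df_sep, df_den = df_sep,
         p = pval, shared_curve = pval >= alpha_level,
         rss_pooled = pooled$rss, rss_separate = rss_sep,
         n_groups = k, n_points = n, model = model,
         alpha_level = alpha_level),
    class = "curve_comparison"
  )
}

#' @export
print.curve_comparison <- function(x, ...) {
  cat(sprintf(
    "Extra-sum-of-squares comparison (%s model, %d groups): F(%d, %d) = %.4g, p = %.4g\n%s\n",
    x$model, x$n_groups, x$df_num, x$df_den, x$F, x$p,
    if (x$shared_curve) "-> one shared curve explains the data" else
      "-> separate curves are required"))
  invisible(x)
}

#' Two-sample Welch t-test on two numeric vectors
#'
#' Thin wrapper around [stats::t.test()] shared by the survival and blot
#' analyses. When both groups have zero variance and equal means the test is
#' degenerate and `t = 0, p = 1` is returned by convention.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return A tibble with columns `t`, `df`, `p`, `mean_a`, `mean_b`.
#' @export
t_test_groups <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  if (var(a) == 0 && var(b) == 0) {
    if (mean(a) == mean(b)) {
      return(tibble::tibble(t = 0, df = NA_real_, p = 1,
                            mean_a = mean(a), mean_b = mean(b)))
    }
    return(tibble::tibble(t = Inf * sign(mean(a) - mean(b)), df = NA_real_,
                          p = 0, mean_a = mean(a), mean_b = mean(b)))
  }
  ht <- t.test(a, b)
  tibble::tibble(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_a = mean(a), mean_b = mean(b))
}
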