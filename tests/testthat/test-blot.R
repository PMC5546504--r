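test_that("band quantification integrates above a straight baseline", {
  # rectangular peak of height 5, width 11 on a zero baseline
  prof <- make_profile(function(x) ifelse(x >= 20 & x <= 31, 5, 0),
                       from = 0, to = 50, n = 5001)
  sig <- quantify_band(prof, c(10, 41))
  expect_equal(sig, 5 * 11, tolerance = 0.01)
  # flat profile has no band
  expect_equal(quantify_band(make_profile(function(x) 7), c(10, 90)), 0)
  expect_error(quantify_band(prof, c(40, 60)), "extent")
  expect_error(quantify_band(prof, c(30, 30)), "lo < hi")
})

test_that("a Gaussian band on a ramp matches the quadrature oracle", {
  f <- function(x) 2 + 0.05 * x + 30 * exp(-(x - 50)^2 / (2 * 4^2))
  prof <- make_profile(f, from = 0, to = 100, n = 4001)
  w <- c(30, 70)
  sig <- quantify_band(prof, w)
  # oracle: adaptive quadrature of (profile - straight chord)
  chord <- function(x) {
    f(w[1]) + (f(w[2]) - f(w[1])) * (x - w[1]) / (w[2] - w[1])
  }
  oracle <- stats::integrate(function(x) f(x) - chord(x), w[1], w[2],
                             rel.tol = 1e-10)$value
  expect_equal(sig, oracle, tolerance = 1e-4)
})

test_that("band signal is additive over windows covering disjoint peaks", {
  f <- function(x) 10 * exp(-(x - 30)^2 / 8) + 20 * exp(-(x - 70)^2 / 8)
  prof <- make_profile(f, from = 0, to = 100, n = 4001)
  whole <- quantify_band(prof, c(10, 90))
  parts <- quantify_band(prof, c(10, 50)) + quantify_band(prof, c(50, 90))
  expect_equal(whole, parts, tolerance = 1e-6)
})

test_that("negative net area is floored at zero with a warning", {
  prof <- make_profile(function(x) ifelse(x > 40 & x < 60, 1, 10),
                       from = 0, to = 100, n = 2001)
  expect_warning(sig <- quantify_band(prof, c(30, 70)), "floored")
  expect_equal(sig, 0)
})

test_that("normalization is relative to loading control and 37 degC", {
  bands <- tibble::tibble(
    cell_line = "HeLa", temperature_C = 42,
    duration_min = c(0, 60, 120),
    target_signal = c(1000, 500, 250),
    control_signal = c(1000, 1000, 500)
  )
  lv <- normalize_levels(bands)
  expect_equal(lv$level, c(100, 50, 50))
  # scale invariance: multiplying every signal in the blot by c changes nothing
  lv2 <- normalize_levels(dplyr::mutate(bands,
                                        target_signal = target_signal * 7,
                                        control_signal = control_signal * 7))
  expect_equal(lv2$level, lv$level)
  expect_error(normalize_levels(dplyr::mutate(bands, control_signal = 0)),
               "positive")
  expect_error(normalize_levels(bands[2:3, ]), "reference")
})

test_that("ANOVA and Tukey HSD match the hand computation on a fixed table", {
  d <- tibble::tibble(
    g = rep(c("a", "b", "c"), each = 5),
    y = c(12.1, 11.8, 12.6, 12.3, 11.9,
          13.4, 13.9, 13.1, 13.7, 13.5,
          11.2, 10.8, 11.5, 11.0, 11.4)
  )
  res <- anova_tukey(d, "y", "g")
  # independent computation from first principles
  k <- 3; n <- 5; N <- 15
  means <- tapply(d$y, d$g, mean)
  gm <- mean(d$y)
  ssb <- n * sum((means - gm)^2)
  ssw <- sum((d$y - means[d$g])^2)
  Fref <- (ssb / (k - 1)) / (ssw / (N - k))
  expect_equal(res$anova$F, Fref, tolerance = 1e-12)
  expect_equal(res$anova$p, pf(Fref, k - 1, N - k, lower.tail = FALSE),
               tolerance = 1e-12)
  mse <- ssw / (N - k)
  for (i in seq_len(nrow(res$tukey))) {
    pair <- strsplit(res$tukey$contrast[i], "-")[[1]]
    q <- abs(unname(means[pair[1]] - means[pair[2]])) / sqrt(mse / n)
    pref <- stats::ptukey(q, k, N - k, lower.tail = FALSE)
    expect_equal(res$tukey$p_adj[i], pref, tolerance = 1e-9)
  }
  # identical groups: F near zero, nothing significant
  same <- tibble::tibble(g = rep(c("a", "b"), each = 4), y = rep(c(1, 2, 3, 4), 2))
  res0 <- anova_tukey(same, "y", "g")
  expect_lt(res0$anova$F, 1e-20)
  expect_false(any(res0$tukey$significant))
})

test_that("Tukey HSD is conservative relative to unadjusted t-tests", {
  set.seed(43)
  d <- tibble::tibble(g = rep(c("a", "b", "c", "d"), each = 4),
                      y = rnorm(16))
  res <- anova_tukey(d, "y", "g")
  means <- tapply(d$y, d$g, mean)
  mse <- sum((d$y - means[d$g])^2) / (16 - 4)
  for (i in seq_len(nrow(res$tukey))) {
    pair <- strsplit(res$tukey$contrast[i], "-")[[1]]
    # unadjusted t on the same contrast with the shared error variance
    tstat <- abs(unname(means[pair[1]] - means[pair[2]])) / sqrt(mse * 2 / 4)
    praw <- 2 * pt(tstat, 12, lower.tail = FALSE)
    expect_gte(res$tukey$p_adj[i] + 1e-12, praw)
  }
})

test_that("Tukey family-wise error stays at or below the nominal level", {
  set.seed(47)
  fam <- replicate(500, {
    d <- tibble::tibble(g = rep(c("a", "b", "c"), each = 4), y = rnorm(12))
    any(anova_tukey(d, "y", "g")$tukey$significant)
  })
  expect_lte(mean(fam), 0.05 + 2 * sqrt(0.05 * 0.95 / 500))
})

test_that("single-replicate groups are excluded with a warning", {
  d <- tibble::tibble(g = c("a", "a", "b", "b", "c"), y = c(1, 2, 3, 4, 9))
  expect_warning(res <- anova_tukey(d, "y", "g"), "excluding")
  expect_equal(res$anova$df_between, 1L)
})

test_that("fractionation analysis separates diverging fraction time courses", {
  # identical series across fractions: one shared curve
  base <- tidyr::crossing(
    fraction = c("whole", "supernatant", "pellet"),
    duration_min = c(0, 15, 30, 60),
    replicate = 1:3
  )
  set.seed(53)
  noise <- rnorm(nrow(base), 0, 2)
  same <- dplyr::mutate(base, level = 100 - 0.5 * duration_min + noise)
  res <- fractionation_analysis(same)
  expect_true(res$comparison$shared_curve)

  # pellet rising while supernatant falls: separate curves, detected often
  set.seed(59)
  hits <- replicate(50, {
    d <- dplyr::mutate(base, level = dplyr::case_when(
      fraction == "whole" ~ 100 - 0.6 * duration_min,
      fraction == "supernatant" ~ 100 - 1.2 * duration_min,
      fraction == "pellet" ~ 100 + 0.8 * duration_min
    ) + rnorm(dplyr::n(), 0, 8))
    d$level <- pmax(d$level, 0)
    !fractionation_analysis(d)$comparison$shared_curve
  })
  expect_gte(mean(hits), 0.9)

  expect_error(fractionation_analysis(same[same$fraction != "pellet", ]),
               "missing fraction")
  expect_error(
    fractionation_analysis(dplyr::filter(same, duration_min <= 15)),
    "at least 3 time points"
  )
})
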