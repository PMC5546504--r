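test_that("plating efficiency is normalized to the 37 degC control", {
  obs <- tibble::tibble(
    cell_line = "HeLa", temperature_C = 43,
    duration_min = c(0, 0, 60, 60), dose_Gy = 0,
    seeded = 200L, colonies = c(100L, 100L, 60L, 60L)
  )
  pe <- plating_efficiency(obs)
  expect_equal(pe$pe, c(0.5, 0.5, 0.3, 0.3))
  expect_equal(pe$pe_norm, c(100, 100, 60, 60))
  expect_error(plating_efficiency(dplyr::mutate(obs, colonies = 0L)), "zero")
})

test_that("synthetic heat kill shows up in normalized plating efficiency", {
  des <- tibble::tibble(temperature_C = 43, duration_min = c(0, 60))
  pep <- dplyr::mutate(des, pe_mult = c(1, 0.6))
  d <- gen_colony_counts(survival_gen_config(
    design = des, doses_Gy = 0, pe_profile = pep, replicates = 60L, seed = 23L
  ))
  pe <- plating_efficiency(d)
  m <- mean(pe$pe_norm[pe$duration_min == 60])
  se <- sd(pe$pe_norm[pe$duration_min == 60]) / sqrt(60)
  expect_lt(abs(m - 60), 4 * se)
})

test_that("linear PE regression recovers exact slopes and flags differences", {
  # noise-free: PE = 100 - 0.2 t
  pe <- tidyr::crossing(temperature_C = c(40, 44), duration_min = c(0, 60, 120, 240)) |>
    dplyr::mutate(pe_norm = ifelse(temperature_C == 40,
                                   100 - 0.05 * duration_min,
                                   100 - 0.2 * duration_min))
  # noise-free fits trigger lm's perfect-fit warning, which is expected here
  fit <- suppressWarnings(fit_pe_linear(pe))
  expect_equal(fit$fits$slope, c(-0.05, -0.2), tolerance = 1e-12)
  expect_false(fit$pairwise$shared_curve[1])
  # constant PE gives slope 0
  flat <- dplyr::mutate(pe, pe_norm = 100)
  expect_equal(suppressWarnings(fit_pe_linear(flat))$fits$slope, c(0, 0),
               tolerance = 1e-12)
  expect_error(fit_pe_linear(pe[pe$duration_min < 100, ]), "3 distinct")
})

test_that("distinct PE slopes at 40 vs 44 degC are detected with high power", {
  des <- thermal_design() |>
    dplyr::filter(temperature_C %in% c(40, 44))
  pep <- default_pe_profile() |>
    dplyr::filter(temperature_C %in% c(40, 44))
  set.seed(31)
  hits <- replicate(60, {
    d <- gen_colony_counts(survival_gen_config(
      design = des, doses_Gy = 0, pe_profile = pep, replicates = 3L,
      seed = sample.int(1e6, 1)
    ))
    pe <- plating_efficiency(d)
    !fit_pe_linear(pe)$pairwise$shared_curve[1]
  })
  expect_gte(mean(hits), 0.9)
})

test_that("surviving fractions are normalized to 0 Gy within condition", {
  obs <- tibble::tibble(
    cell_line = "HeLa", temperature_C = 42, duration_min = 60,
    dose_Gy = c(0, 0, 4), seeded = c(200L, 200L, 800L),
    colonies = c(80L, 80L, 80L)
  )
  sf <- surviving_fraction(obs)
  expect_equal(mean(sf$sf[sf$dose_Gy == 0]), 1)  # exactly
  expect_equal(sf$sf[sf$dose_Gy == 4], 0.25)     # PE 0.1 over PE0 0.4
  expect_error(surviving_fraction(dplyr::mutate(obs, colonies = 0L)), "zero")

  # closed form: empirical SF(2 Gy) near exp(-0.72) for alpha 0.3, beta 0.03
  des <- tibble::tibble(temperature_C = 40, duration_min = 0)
  d <- gen_colony_counts(survival_gen_config(
    design = des, doses_Gy = c(0, 2),
    pe_profile = dplyr::mutate(des, pe_mult = 1), replicates = 400L, seed = 29L
  ))
  sf2 <- surviving_fraction(d)
  m <- mean(sf2$sf[sf2$dose_Gy == 2])
  expect_lt(abs(m - exp(-0.72)), 0.01)
})

test_that("the linear-quadratic fit is exact on noise-free data", {
  d <- tibble::tibble(dose_Gy = rep(c(0, 1, 2, 4, 6), 2))
  d$sf <- exp(-(0.5 * d$dose_Gy + 0.05 * d$dose_Gy^2))
  f <- fit_lq(d)
  expect_equal(f$alpha, 0.5, tolerance = 1e-9)
  expect_equal(f$beta, 0.05, tolerance = 1e-9)
  expect_equal(f$log_norm, 0, tolerance = 1e-9)
  expect_lt(f$rss, 1e-18)
  expect_equal(f$df, f$n_points - 3L)

  # flat survival: alpha = beta = 0
  flat <- tibble::tibble(dose_Gy = c(0, 2, 4, 6), sf = 1)
  f0 <- fit_lq(flat)
  expect_equal(c(f0$alpha, f0$beta, f0$rss), c(0, 0, 0))

  # SF <= 0 points are dropped with a warning; too few doses error
  bad <- tibble::tibble(dose_Gy = c(0, 2, 4, 6), sf = c(1, 0.5, 0, 0.1))
  expect_warning(fit_lq(bad), "SF <= 0")
  expect_error(suppressWarnings(fit_lq(bad[1:3, ])), "3 usable")
})

test_that("the non-negativity constraint binds only when needed", {
  # rising 'survival' forces alpha = beta = 0 under the constraint
  up <- tibble::tibble(dose_Gy = c(0, 2, 4, 6), sf = c(1, 1.2, 1.5, 1.9))
  f <- fit_lq(up)
  expect_true(f$alpha >= 0 && f$beta >= 0)
  expect_true(f$boundary)
  fu <- fit_lq(up, constrain = FALSE)
  expect_lt(fu$alpha, 0)
  expect_lte(fu$rss, f$rss + 1e-12)
})

test_that("identical datasets give a shared curve; rescaling leaves F alone", {
  set.seed(37)
  d1 <- tibble::tibble(dose_Gy = rep(c(0, 2, 4, 6), each = 3))
  d1$sf <- exp(-(0.4 * d1$dose_Gy + 0.04 * d1$dose_Gy^2) + rnorm(12, 0, 0.05))
  both <- dplyr::bind_rows(dplyr::mutate(d1, g = "a"), dplyr::mutate(d1, g = "b"))
  cmp <- compare_curves(both, group = "g", x = "dose_Gy", y = "sf", model = "lq")
  expect_true(cmp$shared_curve)
  expect_equal(cmp$rss_pooled, cmp$rss_separate, tolerance = 1e-9)

  # common rescaling of all SF values is absorbed by the normalization
  scaled <- dplyr::mutate(both, sf = sf * 3.7)
  cmp2 <- compare_curves(scaled, group = "g", x = "dose_Gy", y = "sf", model = "lq")
  expect_equal(cmp2$F, cmp$F, tolerance = 1e-9)
  expect_error(
    compare_curves(both[c(1, 4, 7, 13, 16, 19), ], group = "g",
                   x = "dose_Gy", y = "sf", model = "lq"),
    "insufficient"
  )
})

test_that("Welch t-test wrapper handles regular and degenerate input", {
  r <- t_test_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$t, 0)
  expect_equal(r$p, 1)
  shifted <- t_test_groups(c(1, 2, 3), c(11, 12, 13))
  expect_lt(shifted$p, 0.01)
  ht <- t.test(c(1, 2, 3), c(11, 12, 13))
  expect_equal(shifted$t, unname(ht$statistic))
  # zero variance in both groups
  expect_equal(t_test_groups(c(2, 2), c(2, 2))$p, 1)
  expect_equal(t_test_groups(c(2, 2), c(3, 3))$p, 0)
})

test_that("t-test type-I error is nominal under the null", {
  set.seed(41)
  p <- replicate(2000, t_test_groups(rnorm(5), rnorm(5))$p)
  expect_lt(abs(mean(p < 0.05) - 0.05), 0.02)
})
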