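test_that("maximum projection equals the per-pixel brute-force maximum", {
  set.seed(1)
  stack <- array(sample.int(65535, 16 * 16 * 14, replace = TRUE),
                 dim = c(16, 16, 14))
  proj <- max_project(stack)
  brute <- matrix(0, 16, 16)
  for (i in 1:16) for (j in 1:16) brute[i, j] <- max(stack[i, j, ])
  expect_equal(proj, brute, ignore_attr = TRUE)

  # single bright voxel survives projection; single slice is the identity
  z <- array(0, dim = c(8, 8, 14)); z[3, 5, 7] <- 255
  expect_equal(max_project(z)[3, 5], 255)
  one <- array(runif(64), dim = c(8, 8, 1))
  expect_equal(max_project(one), one[, , 1])
  expect_error(max_project(list()), "empty")
})

test_that("maximum-entropy threshold matches the exhaustive oracle", {
  set.seed(2)
  for (i in 1:200) {
    h <- rpois(256, exp(runif(1, 0, 4)))
    if (sum(h > 0) < 2) next
    expect_identical(max_entropy_threshold(h), brute_force_max_entropy(h))
  }
})

test_that("threshold separates two populations and is shift-equivariant", {
  h <- rep(0, 256); h[11] <- 100; h[201] <- 100
  t0 <- max_entropy_threshold(h)
  expect_gte(t0, 10)
  expect_lt(t0, 200)
  # shifting the histogram by k levels shifts the threshold by k
  set.seed(3)
  h2 <- rpois(200, 3)
  shifted <- c(rep(0, 25), h2)
  expect_equal(max_entropy_threshold(shifted),
               max_entropy_threshold(c(h2, rep(0, 25))) + 25)
  expect_error(max_entropy_threshold(c(0, 5, 0)), "degenerate")
})

test_that("EdU segmentation recovers planted nuclei with high overlap", {
  cfg <- noise_free_cfg(nuclei_per_field = 4L, n_fields = 1L, seed = 13L)
  ds <- gen_image_dataset(cfg)
  proj <- max_project(ds$fields[[1]]$edu)
  rois <- segment_edu_nuclei(proj, cfg$pixel_size_um)
  expect_equal(nrow(rois), 4L)
  # match each ROI to the planted mask by best IoU
  truth_labels <- ds$masks[[1]]
  for (i in seq_len(nrow(rois))) {
    px <- rois$pixels[[i]]
    cand <- unique(truth_labels[px]); cand <- cand[cand != 0]
    ious <- vapply(cand, function(l) {
      tp <- which(truth_labels == l)
      length(intersect(px, tp)) / length(union(px, tp))
    }, numeric(1))
    expect_gt(max(ious), 0.9)
  }
  expect_true(all(rois$edu_positive))

  blank <- matrix(100, 64, 64)
  expect_equal(nrow(segment_edu_nuclei(blank, 0.1)), 0L)
})

test_that("dim nuclei are segmented but gated out by EdU positivity", {
  # one bright and one barely-stained nucleus on a noisy background: with an
  # explicit segmentation threshold the dim nucleus is still returned, but
  # its mean EdU falls below background + 3 SD so it is flagged negative
  set.seed(17)
  img <- matrix(rnorm(300 * 300, 200, 20), 300, 300)
  disk <- function(cx, cy, r) {
    rc <- expand.grid(row = 1:300, col = 1:300)
    which((rc$col - cx)^2 + (rc$row - cy)^2 <= r^2)
  }
  bright <- disk(80, 80, 55)
  dim_px <- disk(220, 220, 55)
  img[bright] <- img[bright] + 5000
  img[dim_px] <- img[dim_px] + 40
  rois <- segment_edu_nuclei(img, pixel_size_um = 0.1, threshold = 230,
                             min_area_um2 = 20)
  expect_equal(nrow(rois), 2L)
  bright_roi <- which.max(rois$mean_edu)
  expect_true(rois$edu_positive[bright_roi])
  expect_false(rois$edu_positive[-bright_roi])
})

test_that("focus detection is exact on noise-free planted spots", {
  cfg <- noise_free_cfg(
    nuclei_per_field = 5L, n_fields = 2L, seed = 11L,
    category_mix = c(1, 0, 0), focus_count_mean = c(12, 4, 30)
  )
  ds <- gen_image_dataset(cfg)
  an <- analyze_foci(ds)
  m <- match_truth(an$profiles, an$rois, ds$nuclei, cfg$pixel_size_um)
  # recall = precision = 1: every planted spot found, nothing extra
  expect_equal(m$focus_count, m$true_n_foci)
  # every detected focus sits on a planted centre (within 3 pixels)
  for (i in seq_len(nrow(an$foci))) {
    fc <- an$foci[i, ]
    tr <- ds$foci[ds$foci$field == fc$field, ]
    d <- sqrt((tr$x_px - fc$cx)^2 + (tr$y_px - fc$cy)^2)
    expect_lt(min(d), 3)
  }
  # integrated density is exactly area times mean intensity
  expect_equal(an$foci$integrated_density,
               an$foci$area_um2 * an$foci$mean_intensity)
})

test_that("uniform nuclei yield zero foci with a degenerate-histogram warning", {
  img <- matrix(500, 64, 64)
  px <- which(matrix(TRUE, 64, 64))[1000:2000]
  expect_warning(fc <- detect_foci(img, px, 0.1), "degenerate")
  expect_equal(nrow(fc), 0L)
})

test_that("raising the minimum area bound never increases the focus count", {
  cfg <- noise_free_cfg(nuclei_per_field = 3L, n_fields = 1L, seed = 19L,
                        category_mix = c(1, 0, 0))
  ds <- gen_image_dataset(cfg)
  rad <- max_project(ds$fields[[1]]$rad51)
  edu <- max_project(ds$fields[[1]]$edu)
  rois <- segment_edu_nuclei(edu, cfg$pixel_size_um)
  counts <- sapply(c(0.01, 0.05, 0.2, 0.5, 1), function(mn) {
    sum(vapply(rois$pixels, function(px) {
      nrow(detect_foci(rad, px, cfg$pixel_size_um, min_size_um2 = mn))
    }, numeric(1)))
  })
  expect_true(all(diff(counts) <= 0))
})

test_that("per-nucleus profiles summarize foci correctly", {
  rois <- tibble::tibble(nucleus_id = 1:2, mean_edu = c(5000, 6000),
                         edu_positive = TRUE)
  foci <- tibble::tibble(
    nucleus_id = c(1, 1, 1),
    area_um2 = c(2, 1, 1),
    mean_intensity = c(50, 10, 30),
    integrated_density = c(100, 10, 30)
  )
  pr <- profile_nuclei(foci, rois)
  expect_equal(pr$focus_count, c(3L, 0L))
  # mean over foci of per-focus integrated density, not product of means
  expect_equal(pr$mean_integrated_density[1], mean(c(100, 10, 30)))
  expect_true(is.na(pr$mean_integrated_density[2]))
  expect_true(is.na(pr$mean_area_um2[2]))
  expect_equal(pr$mean_edu_intensity, c(5000, 6000))
})

test_that("category calls follow the count/density rules against a reference", {
  set.seed(4)
  ref <- tibble::tibble(
    focus_count = rpois(100, 20),
    mean_integrated_density = rnorm(100, 3000, 400),
    mean_edu_intensity = 8000, edu_positive = TRUE, nucleus_id = 1:100
  )
  probes <- tibble::tibble(
    nucleus_id = 1:4,
    focus_count = c(median(ref$focus_count), 3L, 30L, 0L),
    mean_integrated_density = c(stats::median(ref$mean_integrated_density),
                                3000, 100, NA),
    mean_edu_intensity = 8000, edu_positive = TRUE
  )
  cl <- classify_category(probes, ref)
  expect_equal(cl$category, c(1L, 2L, 3L, NA))
  expect_error(classify_category(probes, ref[1:10, ]), "at least 20")
  expect_error(classify_category(probes, NULL), "reference")
})

test_that("2-D feature histogram marginalizes to the 1-D histograms", {
  set.seed(5)
  pr <- tibble::tibble(
    focus_count = rpois(200, 15) + 1L,
    mean_integrated_density = stats::rlnorm(200, 7, 0.5)
  )
  cb <- seq(0, 50, by = 5)
  db <- seq(0, max(pr$mean_integrated_density) + 1, length.out = 11)
  h2 <- feature_histogram2d(pr, count_bins = cb, density_bins = db)
  expect_equal(sum(h2$n), 200L)
  marg <- h2 |>
    dplyr::group_by(count_mid) |>
    dplyr::summarise(n = sum(n))
  h1 <- graphics::hist(pr$focus_count, breaks = cb, right = FALSE,
                       plot = FALSE)$counts
  expect_equal(marg$n, h1[h1 > 0])
  # identical profiles land in one bin
  two <- feature_histogram2d(pr[c(1, 1), ])
  expect_equal(nrow(two), 1L)
  expect_equal(two$n, 2L)
})

test_that("EdU differences between categories are recovered and tested", {
  set.seed(6)
  pr <- tibble::tibble(
    category = rep(c(1L, 3L), each = 40),
    mean_edu_intensity = c(rnorm(40, 8000, 800), rnorm(40, 4000, 500))
  )
  res <- edu_by_category(pr)
  ratio <- res$summary$mean_edu[res$summary$category == 3] /
    res$summary$mean_edu[res$summary$category == 1]
  se_ratio <- 3 * sqrt(sum((res$summary$se_edu / res$summary$mean_edu)^2)) * ratio
  expect_lt(abs(ratio - 0.5), se_ratio)
  expect_lt(res$tests$p[1], 1e-6)
  expect_error(edu_by_category(pr[pr$category == 1, ]), "at least 2")
  expect_warning(
    edu_by_category(dplyr::bind_rows(
      pr, tibble::tibble(category = 2L, mean_edu_intensity = 7000)
    )),
    "excluding"
  )
})
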