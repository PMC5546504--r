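#' Maximum-intensity projection of a Z-stack
#'
#' @param stack numeric 3-D array (rows x cols x slices) or a list of
#'   equally sized matrices.
#' @return A matrix: the per-pixel maximum over slices.
#' @examples
#' max_project(array(1:8, c(2, 2, 2)))
#' @export
max_project <- function(stack) {
  if (is.list(stack)) {
    if (length(stack) == 0L) abort("empty stack")
    return(Reduce(pmax, stack))
  }
  if (!(is.array(stack) && length(dim(stack)) == 3L)) {
    abort("`stack` must be a 3-D array or a list of matrices")
  }
  if (dim(stack)[3] == 0L) abort("empty stack")
  Reduce(pmax, asplit(stack, 3L))
}

#' Maximum-entropy (Kapur) threshold of a histogram
#'
#' Selects the split that maximizes the sum of the Shannon entropies of the
#' normalized background and foreground class histograms. The returned value
#' is the level of the last background bin: pixels with values strictly
#' greater belong to the foreground. Ties are broken toward the lowest
#' threshold. Candidate splits leave nonzero mass in both classes.
#'
#' @param counts non-negative histogram counts.
#' @param levels gray level of each bin (default `0:(length(counts) - 1)`).
#' @return The threshold level (an element of `levels`).
#' @examples
#' h <- rep(0, 256); h[11] <- 100; h[201] <- 100
#' max_entropy_threshold(h)  # separates the two populations
#' @export
max_entropy_threshold <- function(counts, levels = seq_along(counts) - 1) {
  stopifnot(length(counts) == length(levels), all(counts >= 0))
  if (sum(counts > 0) < 2L) {
    abort("degenerate histogram: fewer than 2 nonzero bins")
  }
  p <- counts / sum(counts)
  plogp <- ifelse(p > 0, p * log(p), 0)
  P1 <- cumsum(p)
  A <- cumsum(plogp)
  n <- length(p)
  tot <- A[n]
  cand <- which(P1 > 0 & P1 < 1)
  cand <- cand[cand < n]
  H <- log(P1[cand]) - A[cand] / P1[cand] +
    log(1 - P1[cand]) - (tot - A[cand]) / (1 - P1[cand])
  levels[cand[which.max(H)]]
}

# 256-bin histogram over a fixed gray range; returns counts, breaks and the
# intensity cutoff implied by a chosen background bin.
image_histogram <- function(values, n_bins = 256L, max_gray = 65535) {
  breaks <- seq(0, max_gray, length.out = n_bins + 1L)
  idx <- findInterval(values, breaks, rightmost.closed = TRUE)
  idx[idx < 1L] <- 1L
  idx[idx > n_bins] <- n_bins
  list(counts = tabulate(idx, nbins = n_bins), breaks = breaks)
}

#' Segment EdU-stained nuclei in a projected image
#'
#' Thresholds the EdU channel globally (maximum-entropy threshold by
#' default), labels connected components and keeps those above a minimum
#' nucleus area. Each region of interest carries its mean EdU intensity and
#' an `edu_positive` flag: mean EdU above the background mean plus
#' `edu_positive_k` background standard deviations (S-phase gating).
#'
#' @param edu_image 2-D numeric matrix (projected EdU channel).
#' @param pixel_size_um pixel size in micrometres.
#' @param threshold numeric global threshold, or `NULL` to derive one from
#'   robust background statistics (`median + seg_k * 1.4826 * MAD`; most of
#'   the field is background, so the median and MAD estimate the background
#'   level and noise). This deliberately separates background from nuclei of
#'   any staining intensity — dim S-phase-compromised nuclei must still be
#'   segmented and are only flagged by the positivity gate.
#' @param seg_k background MAD multiples for the automatic threshold.
#' @param min_area_um2 minimum nucleus area (square micrometres).
#' @param edu_positive_k number of background standard deviations above the
#'   background mean that the mean ROI EdU signal must exceed.
#' @param max_gray full-scale gray value of the image.
#' @return A tibble with one row per nucleus: `nucleus_id`, `area_um2`,
#'   `cx`, `cy` (pixel centroid), `mean_edu`, `edu_positive` and a `pixels`
#'   list-column of matrix indices. The label matrix is attached as
#'   attribute `"labels"`. An all-background image yields zero rows.
#' @export
segment_edu_nuclei <- function(edu_image, pixel_size_um,
                               threshold = NULL, seg_k = 6,
                               min_area_um2 = 20,
                               edu_positive_k = 3, max_gray = 65535) {
  stopifnot(is.matrix(edu_image), pixel_size_um > 0)
  empty <- tibble::tibble(
    nucleus_id = integer(), area_um2 = numeric(), cx = numeric(),
    cy = numeric(), mean_edu = numeric(), edu_positive = logical(),
    pixels = list()
  )
  rng <- range(edu_image)
  if (rng[1] == rng[2]) {
    attr(empty, "labels") <- matrix(0L, nrow(edu_image), ncol(edu_image))
    return(empty)
  }
  if (is.null(threshold)) {
    threshold <- stats::median(edu_image) +
      seg_k * stats::mad(edu_image, constant = 1.4826)
  }
  mask <- edu_image > threshold
  labels <- round(EBImage::bwlabel(mask))
  px_area <- pixel_size_um^2
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0L) {
    attr(empty, "labels") <- labels
    return(empty)
  }
  rows <- purrr::map_dfr(ids, function(i) {
    px <- which(labels == i)
    area <- length(px) * px_area
    if (area < min_area_um2) return(NULL)
    rc <- arrayInd(px, dim(edu_image))
    tibble::tibble(
      nucleus_id = i,
      area_um2 = area,
      # pixel-centred, 0-based coordinates
      cx = mean(rc[, 2]) - 1, cy = mean(rc[, 1]) - 1,
      mean_edu = mean(edu_image[px]),
      pixels = list(px)
    )
  })
  if (nrow(rows) == 0L) {
    attr(empty, "labels") <- labels
    return(empty)
  }
  keep_px <- unlist(rows$pixels)
  bg <- edu_image[-keep_px]
  cutoff <- mean(bg) + edu_positive_k * sd(bg)
  rows <- rows |>
    dplyr::mutate(edu_positive = .data$mean_edu > cutoff,
                  nucleus_id = dplyr::row_number()) |>
    dplyr::select("nucleus_id", "area_um2", "cx", "cy", "mean_edu",
                  "edu_positive", "pixels")
  attr(rows, "labels") <- labels
  attr(rows, "edu_cutoff") <- cutoff
  rows
}

#' Detect RAD51 foci within one nucleus
#'
#' Thresholds the RAD51 pixels inside the nucleus mask with the
#' maximum-entropy algorithm (256-bin histogram over the full gray range),
#' labels connected supra-threshold components and keeps particles whose
#' area falls within the configured bounds. Per focus, the area (square
#' micrometres), mean intensity and integrated density
#' (area x mean intensity) are reported.
#'
#' @param rad51_image 2-D numeric matrix (projected RAD51 channel).
#' @param roi_pixels integer matrix indices of the nucleus mask.
#' @param pixel_size_um pixel size in micrometres.
#' @param min_size_um2,max_size_um2 particle-size bounds in square
#'   micrometres (defaults 0.05 and 5).
#' @param max_gray full-scale gray value of the image.
#' @return A tibble with one row per focus: `focus_id`, `area_um2`,
#'   `mean_intensity`, `integrated_density`, `n_px`, `cx`, `cy`. A nucleus
#'   whose RAD51 histogram is degenerate yields zero foci with a warning.
#' @export
detect_foci <- function(rad51_image, roi_pixels, pixel_size_um,
                        min_size_um2 = 0.05, max_size_um2 = 5,
                        max_gray = 65535) {
  stopifnot(is.matrix(rad51_image), length(roi_pixels) > 0, pixel_size_um > 0)
  empty <- tibble::tibble(
    focus_id = integer(), area_um2 = numeric(), mean_intensity = numeric(),
    integrated_density = numeric(), n_px = integer(),
    cx = numeric(), cy = numeric()
  )
  vals <- rad51_image[roi_pixels]
  h <- image_histogram(vals, max_gray = max_gray)
  if (sum(h$counts > 0) < 2L) {
    warn("degenerate RAD51 histogram inside ROI; no foci detected")
    return(empty)
  }
  bin <- max_entropy_threshold(h$counts, levels = seq_along(h$counts))
  cutoff <- h$breaks[bin + 1L]
  mask <- matrix(FALSE, nrow(rad51_image), ncol(rad51_image))
  mask[roi_pixels] <- rad51_image[roi_pixels] > cutoff
  labels <- round(EBImage::bwlabel(mask))
  ids <- setdiff(sort(unique(as.integer(labels))), 0L)
  if (length(ids) == 0L) return(empty)
  px_area <- pixel_size_um^2
  out <- purrr::map_dfr(ids, function(i) {
    px <- which(labels == i)
    area <- length(px) * px_area
    if (area < min_size_um2 || area > max_size_um2) return(NULL)
    rc <- arrayInd(px, dim(rad51_image))
    mi <- mean(rad51_image[px])
    tibble::tibble(
      area_um2 = area, mean_intensity = mi,
      integrated_density = area * mi,
      n_px = length(px), cx = mean(rc[, 2]) - 1, cy = mean(rc[, 1]) - 1
    )
  })
  if (nrow(out) == 0L) return(empty)
  dplyr::mutate(out, focus_id = dplyr::row_number()) |>
    dplyr::select("focus_id", "area_um2", "mean_intensity",
                  "integrated_density", "n_px", "cx", "cy")
}

#' Per-nucleus focus statistics
#'
#' Summarizes detected foci per nucleus: focus count, mean area, mean
#' intensity and the mean integrated density per focus (the mean over foci
#' of each focus's area x mean intensity). Nuclei without foci are reported
#' with count 0 and undefined (`NA`) morphology statistics.
#'
#' @param foci tibble of detected foci with a `nucleus_id` column (rows from
#'   [detect_foci()] bound together).
#' @param rois tibble of nuclei from [segment_edu_nuclei()].
#' @return A tibble with one row per nucleus: `nucleus_id`, `focus_count`,
#'   `mean_area_um2`, `mean_intensity`, `mean_integrated_density`,
#'   `mean_edu_intensity`, `edu_positive`.
#' @export
profile_nuclei <- function(foci, rois) {
  stopifnot("nucleus_id" %in% names(rois))
  stats <- if (nrow(foci) > 0) {
    stopifnot("nucleus_id" %in% names(foci))
    foci |>
      dplyr::group_by(.data$nucleus_id) |>
      dplyr::summarise(
        focus_count = dplyr::n(),
        mean_area_um2 = mean(.data$area_um2),
        mean_intensity = mean(.data$mean_intensity),
        mean_integrated_density = mean(.data$integrated_density),
        .groups = "drop"
      )
  } else {
    tibble::tibble(nucleus_id = integer(), focus_count = integer(),
                   mean_area_um2 = numeric(), mean_intensity = numeric(),
                   mean_integrated_density = numeric())
  }
  rois |>
    dplyr::select("nucleus_id", mean_edu_intensity = "mean_edu",
                  "edu_positive") |>
    dplyr::left_join(stats, by = "nucleus_id") |>
    dplyr::mutate(focus_count = dplyr::coalesce(.data$focus_count, 0L)) |>
    dplyr::select("nucleus_id", "focus_count", "mean_area_um2",
                  "mean_intensity", "mean_integrated_density",
                  "mean_edu_intensity", "edu_positive")
}

#' Classify nuclei into RAD51 focus-morphology categories
#'
#' Rule-based call in the (focus count, mean integrated density) plane
#' against a reference distribution of control-condition nuclei:
#' category 3 (many small, dim foci — the stalled-replication-fork
#' morphology) when the mean integrated density falls below the low-density
#' cutoff; otherwise category 2 (few large foci — attenuated recombination)
#' when the focus count falls below the low-count cutoff; otherwise
#' category 1 (normal focus formation). Cutoffs are quantiles of the
#' reference profiles. Zero-focus nuclei are unclassifiable (`NA`).
#'
#' @param profiles tibble from [profile_nuclei()].
#' @param reference tibble of control-condition profiles (same columns);
#'   at least 20 classifiable nuclei are required.
#' @param low_count_q,low_density_q reference quantiles defining the
#'   low-count and low-density cutoffs.
#' @return `profiles` with an integer `category` column appended; the
#'   cutoffs are attached as attribute `"cutoffs"`.
#' @export
classify_category <- function(profiles, reference,
                              low_count_q = 0.01, low_density_q = 0.01) {
  if (missing(reference) || is.null(reference)) {
    abort("a reference set of control-condition profiles is required")
  }
  ref <- dplyr::filter(reference, .data$focus_count > 0,
                       is.finite(.data$mean_integrated_density))
  if (nrow(ref) < 20L) {
    abort("reference must contain at least 20 classifiable control nuclei")
  }
  low_count <- quantile(ref$focus_count, low_count_q, names = FALSE)
  low_density <- quantile(ref$mean_integrated_density, low_density_q,
                          names = FALSE)
  out <- dplyr::mutate(
    profiles,
    category = dplyr::case_when(
      .data$focus_count == 0 ~ NA_integer_,
      .data$mean_integrated_density < low_density ~ 3L,
      .data$focus_count < low_count ~ 2L,
      TRUE ~ 1L
    )
  )
  attr(out, "cutoffs") <- c(low_count = low_count, low_density = low_density)
  out
}

#' 2-D histogram of focus count versus mean integrated density
#'
#' Bins the per-nucleus (focus count, mean integrated density) pairs — the
#' plane in which the three focus morphologies separate — into a 2-D table.
#'
#' @param profiles tibble from [profile_nuclei()]; nuclei with undefined
#'   density (zero foci) are excluded.
#' @param count_bins,density_bins number of bins (or explicit break
#'   vectors) along each axis.
#' @return A tibble with `count_mid`, `density_mid`, `n` per nonzero bin;
#'   bin breaks are attached as attributes `"count_breaks"` and
#'   `"density_breaks"`. Bin counts sum to the number of usable nuclei.
#' @export
feature_histogram2d <- function(profiles, count_bins = 20, density_bins = 20) {
  d <- dplyr::filter(profiles, .data$focus_count > 0,
                     is.finite(.data$mean_integrated_density))
  if (nrow(d) == 0L) abort("no nuclei with defined focus statistics")
  mk_breaks <- function(x, b) {
    if (length(b) > 1L) return(b)
    r <- range(x)
    if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
    seq(r[1], r[2], length.out = b + 1L)
  }
  cb <- mk_breaks(d$focus_count, count_bins)
  db <- mk_breaks(d$mean_integrated_density, density_bins)
  ci <- pmin(pmax(findInterval(d$focus_count, cb, rightmost.closed = TRUE), 1L),
             length(cb) - 1L)
  di <- pmin(pmax(findInterval(d$mean_integrated_density, db,
                               rightmost.closed = TRUE), 1L),
             length(db) - 1L)
  mids <- function(b) (b[-1] + b[-length(b)]) / 2
  out <- tibble::tibble(ci = ci, di = di) |>
    dplyr::count(.data$ci, .data$di, name = "n") |>
    dplyr::transmute(count_mid = mids(cb)[.data$ci],
                     density_mid = mids(db)[.data$di], n = .data$n)
  attr(out, "count_breaks") <- cb
  attr(out, "density_breaks") <- db
  out
}

#' EdU intensity by focus-morphology category
#'
#' Compares the mean EdU (DNA-synthesis) signal across focus categories:
#' per-category mean and standard error plus all pairwise Welch t-tests.
#' Categories with fewer than 2 nuclei are excluded with a warning.
#'
#' @param profiles classified profiles (from [classify_category()]).
#' @return A list of class `edu_category_result` with `summary` (per
#'   category: n, mean, se) and `tests` (pairwise t-tests).
#' @export
edu_by_category <- function(profiles) {
  stopifnot(all(c("category", "mean_edu_intensity") %in% names(profiles)))
  d <- dplyr::filter(profiles, !is.na(.data$category))
  sizes <- table(d$category)
  small <- names(sizes)[sizes < 2L]
  if (length(small)) {
    warn(sprintf("excluding categories with < 2 nuclei: %s",
                 paste(small, collapse = ", ")))
    d <- dplyr::filter(d, !.data$category %in% as.integer(small))
  }
  cats <- sort(unique(d$category))
  if (length(cats) < 2L) {
    abort("need at least 2 categories with >= 2 nuclei each")
  }
  summ <- d |>
    dplyr::group_by(.data$category) |>
    dplyr::summarise(
      n = dplyr::n(),
      mean_edu = mean(.data$mean_edu_intensity),
      se_edu = sd(.data$mean_edu_intensity) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  pairs <- utils::combn(cats, 2L, simplify = FALSE)
  tests <- purrr::map_dfr(pairs, function(pr) {
    a <- d$mean_edu_intensity[d$category == pr[1]]
    b <- d$mean_edu_intensity[d$category == pr[2]]
    dplyr::bind_cols(tibble::tibble(category_a = pr[1], category_b = pr[2]),
                     t_test_groups(a, b))
  })
  structure(list(summary = summ, tests = tests),
            class = "edu_category_result")
}

#' @export
print.edu_category_result <- function(x, ...) {
  cat("EdU intensity by focus category:\n")
  print(x$summary)
  cat("\nPairwise Welch t-tests:\n")
  print(x$tests)
  invisible(x)
}
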