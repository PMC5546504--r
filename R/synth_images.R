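#' Configuration for the synthetic two-channel microscopy generator
#'
#' Defaults reproduce the acquisition geometry of the focus-counting assay
#' (1024 x 1024 pixels spanning 82 x 82 um, 14-slice Z-stacks at 1 um
#' increment) and three focus morphologies: category 1 nuclei carry many
#' bright foci of normal size ("normal" recombination), category 2 nuclei
#' few large bright foci (attenuated recombination), category 3 nuclei many
#' very small dim foci with a reduced EdU signal (stalled replication
#' forks). All per-category parameters are vectors of length 3 in category
#' order.
#'
#' @param image_width_px,image_height_px image size in pixels (>= 64).
#' @param pixel_size_um pixel size (um/pixel).
#' @param n_slices Z-slices per stack (>= 1), 1 um apart.
#' @param n_fields number of fields (stacks) to generate.
#' @param nuclei_per_field nuclei placed per field (0 allowed: pure noise).
#' @param category_mix proportions of categories 1-3, summing to 1.
#' @param focus_count_mean,focus_count_dispersion per-category focus-count
#'   distribution: Poisson with the given mean, or negative binomial when
#'   the dispersion (size) is finite.
#' @param focus_sigma_um per-category Gaussian focus radius (um, the spot
#'   sigma in XY).
#' @param focus_sigma_cv,focus_peak_cv,edu_cv lognormal coefficients of
#'   variation of radius, peak intensity and per-nucleus EdU level.
#' @param focus_peak per-category focus peak intensity (a.u. above the
#'   nucleoplasm level).
#' @param edu_intensity_mean per-category mean nuclear EdU intensity (a.u.).
#' @param nucleus_radius_um mean nucleus semi-axis (um).
#' @param nucleus_axis_jitter relative jitter of the two ellipse semi-axes.
#' @param rad51_nucleoplasm diffuse RAD51 signal inside nuclei (a.u.).
#' @param background_level camera background offset (a.u.).
#' @param noise_sd Gaussian read-noise standard deviation (0 disables).
#' @param gain shot-noise gain: pixel values are Poisson-resampled as
#'   `rpois(signal / gain) * gain` (0 disables shot noise).
#' @param separation_factor minimum focus-centre separation, in units of the
#'   category's focus sigma.
#' @param focus_sigma_z_um axial sigma of planted foci (um).
#' @param seed integer seed; field f uses substream `seed + 1000 * (f - 1)`.
#' @return A list of class `image_gen_config`.
#' @export
image_gen_config <- function(image_width_px = 1024L,
                             image_height_px = 1024L,
                             pixel_size_um = 82 / 1024,
                             n_slices = 14L,
                             n_fields = 1L,
                             nuclei_per_field = 8L,
                             category_mix = c(1, 1, 1) / 3,
                             focus_count_mean = c(20, 4, 30),
                             focus_count_dispersion = c(Inf, Inf, Inf),
                             focus_sigma_um = c(0.25, 0.45, 0.16),
                             focus_sigma_cv = 0.08,
                             focus_peak = c(10000, 12000, 3500),
                             focus_peak_cv = 0.15,
                             edu_intensity_mean = c(8000, 8000, 4000),
                             edu_cv = 0.10,
                             nucleus_radius_um = 5,
                             nucleus_axis_jitter = 0.15,
                             rad51_nucleoplasm = 800,
                             background_level = 200,
                             noise_sd = 50,
                             gain = 1,
                             separation_factor = 4.5,
                             focus_sigma_z_um = 1,
                             seed = 1L) {
  stopifnot(
    image_width_px >= 64L, image_height_px >= 64L,
    n_slices >= 1L, n_fields >= 1L, nuclei_per_field >= 0L,
    pixel_size_um > 0,
    length(category_mix) == 3L, all(category_mix >= 0), all(category_mix <= 1),
    abs(sum(category_mix) - 1) < 1e-9,
    length(focus_count_mean) == 3L, length(focus_sigma_um) == 3L,
    length(focus_peak) == 3L, length(edu_intensity_mean) == 3L,
    noise_sd >= 0, gain >= 0, background_level >= 0
  )
  structure(
    list(
      image_width_px = as.integer(image_width_px),
      image_height_px = as.integer(image_height_px),
      pixel_size_um = pixel_size_um,
      n_slices = as.integer(n_slices),
      n_fields = as.integer(n_fields),
      nuclei_per_field = as.integer(nuclei_per_field),
      category_mix = category_mix,
      focus_count_mean = focus_count_mean,
      focus_count_dispersion = focus_count_dispersion,
      focus_sigma_um = focus_sigma_um,
      focus_sigma_cv = focus_sigma_cv,
      focus_peak = focus_peak,
      focus_peak_cv = focus_peak_cv,
      edu_intensity_mean = edu_intensity_mean,
      edu_cv = edu_cv,
      nucleus_radius_um = nucleus_radius_um,
      nucleus_axis_jitter = nucleus_axis_jitter,
      rad51_nucleoplasm = rad51_nucleoplasm,
      background_level = background_level,
      noise_sd = noise_sd,
      gain = gain,
      separation_factor = separation_factor,
      focus_sigma_z_um = focus_sigma_z_um,
      seed = as.integer(seed)
    ),
    class = "image_gen_config"
  )
}

# Sample non-overlapping elliptical nuclei; bounded retries, error on failure.
place_nuclei <- function(cfg) {
  ps <- cfg$pixel_size_um
  w_um <- cfg$image_width_px * ps
  h_um <- cfg$image_height_px * ps
  placed <- list()
  for (j in seq_len(cfg$nuclei_per_field)) {
    ok <- FALSE
    for (try in 1:500) {
      a <- cfg$nucleus_radius_um * (1 + runif(1, -1, 1) * cfg$nucleus_axis_jitter)
      b <- cfg$nucleus_radius_um * (1 + runif(1, -1, 1) * cfg$nucleus_axis_jitter)
      theta <- runif(1, 0, pi)
      r <- max(a, b)
      if (2 * r + 2 > min(w_um, h_um)) next
      cx <- runif(1, r + 1, w_um - r - 1)
      cy <- runif(1, r + 1, h_um - r - 1)
      clear <- all(purrr::map_lgl(placed, function(p) {
        sqrt((p$cx - cx)^2 + (p$cy - cy)^2) > r + max(p$a, p$b) + 0.5
      }))
      if (clear) {
        placed[[j]] <- list(cx = cx, cy = cy, a = a, b = b, theta = theta)
        ok <- TRUE
        break
      }
    }
    if (!ok) {
      abort(sprintf(
        "could not place %d non-overlapping nuclei in a %.0f x %.0f um field",
        cfg$nuclei_per_field, w_um, h_um))
    }
  }
  placed
}

# Pixel mask of one elliptical nucleus; returns matrix indices.
ellipse_pixels <- function(nuc, cfg) {
  ps <- cfg$pixel_size_um
  r <- max(nuc$a, nuc$b)
  cols <- max(1L, floor((nuc$cx - r) / ps)):min(cfg$image_width_px,
                                               ceiling((nuc$cx + r) / ps))
  rows <- max(1L, floor((nuc$cy - r) / ps)):min(cfg$image_height_px,
                                                ceiling((nuc$cy + r) / ps))
  # pixel centres, 0-based convention: centre of pixel (i, j) is at
  # ((j - 0.5) * ps, (i - 0.5) * ps)
  xs <- (cols - 0.5) * ps - nuc$cx
  ys <- (rows - 0.5) * ps - nuc$cy
  dx <- matrix(xs, nrow = length(rows), ncol = length(cols), byrow = TRUE)
  dy <- matrix(ys, nrow = length(rows), ncol = length(cols))
  u <- (dx * cos(nuc$theta) + dy * sin(nuc$theta)) / nuc$a
  v <- (-dx * sin(nuc$theta) + dy * cos(nuc$theta)) / nuc$b
  inside <- u^2 + v^2 <= 1
  rc <- which(inside, arr.ind = TRUE)
  (cols[rc[, 2]] - 1L) * cfg$image_height_px + rows[rc[, 1]]
}

# Sample focus centres inside the (slightly shrunken) ellipse with a
# category-dependent minimum separation; skips centres that cannot be
# placed after bounded retries.
sample_focus_centres <- function(nuc, n, min_sep, cfg) {
  pts <- matrix(numeric(0), ncol = 2)
  for (i in seq_len(n)) {
    for (try in 1:200) {
      phi <- runif(1, 0, 2 * pi)
      rad <- 0.85 * sqrt(runif(1))
      ex <- rad * nuc$a * cos(phi)
      ey <- rad * nuc$b * sin(phi)
      x <- nuc$cx + ex * cos(nuc$theta) - ey * sin(nuc$theta)
      y <- nuc$cy + ex * sin(nuc$theta) + ey * cos(nuc$theta)
      if (nrow(pts) == 0 ||
          all(sqrt((pts[, 1] - x)^2 + (pts[, 2] - y)^2) >= min_sep)) {
        pts <- rbind(pts, c(x, y))
        break
      }
    }
  }
  pts
}

apply_camera_noise <- function(signal, cfg) {
  v <- signal
  if (cfg$gain > 0) {
    v <- rpois(length(v), v / cfg$gain) * cfg$gain
  }
  if (cfg$noise_sd > 0) {
    v <- v + rnorm(length(v), 0, cfg$noise_sd)
  }
  matrix(pmin(65535, pmax(0, round(v))), nrow = nrow(signal))
}

#' Generate a synthetic two-channel Z-stack dataset with ground truth
#'
#' Produces, per field, an EdU channel (uniform nuclear stain at a
#' per-nucleus level drawn from its category) and a RAD51 channel (diffuse
#' nucleoplasmic signal plus 3-D Gaussian foci planted only inside nucleus
#' masks), with Poisson shot noise and Gaussian read noise. Identical seeds
#' give bit-identical stacks; each field uses an independent substream.
#'
#' @param cfg an [image_gen_config()].
#' @return A list of class `image_dataset`:
#'   \describe{
#'     \item{fields}{list of fields, each `list(edu = , rad51 = )` of
#'       rows x cols x slices integer-valued arrays.}
#'     \item{nuclei}{ground-truth tibble: `field`, `nucleus_id`, `category`,
#'       `cx_um`, `cy_um`, `a_um`, `b_um`, `theta`, `edu_level`, `n_foci`.}
#'     \item{foci}{ground-truth tibble: `field`, `nucleus_id`, `x_px`,
#'       `y_px` (0-based pixel coordinates), `z`, `sigma_um`, `peak`.}
#'     \item{masks}{list of integer label matrices (0 = background,
#'       label = `nucleus_id`).}
#'     \item{config}{the generating configuration.}
#'   }
#' @examples
#' ds <- gen_image_dataset(image_gen_config(
#'   image_width_px = 128, image_height_px = 128, n_slices = 3,
#'   nuclei_per_field = 1, seed = 2))
#' ds$nuclei
#' @export
gen_image_dataset <- function(cfg = image_gen_config()) {
  stopifnot(inherits(cfg, "image_gen_config"))
  fields <- vector("list", cfg$n_fields)
  masks <- vector("list", cfg$n_fields)
  nuc_tbl <- list()
  foci_tbl <- list()
  ps <- cfg$pixel_size_um
  h <- cfg$image_height_px
  w <- cfg$image_width_px

  for (f in seq_len(cfg$n_fields)) {
    with_seed(cfg$seed + 1000L * (f - 1L), {
      nucs <- place_nuclei(cfg)
      labels <- matrix(0L, h, w)
      edu_sig <- matrix(cfg$background_level, h, w)
      rad_base <- matrix(cfg$background_level, h, w)
      field_foci <- list()

      for (j in seq_along(nucs)) {
        nuc <- nucs[[j]]
        px <- ellipse_pixels(nuc, cfg)
        labels[px] <- j
        cat_j <- sample.int(3L, 1L, prob = cfg$category_mix)
        edu_level <- cfg$edu_intensity_mean[cat_j] * rlnorm_cv(1, cfg$edu_cv)
        edu_sig[px] <- cfg$background_level + edu_level
        rad_base[px] <- cfg$background_level + cfg$rad51_nucleoplasm

        disp <- cfg$focus_count_dispersion[cat_j]
        n_foci <- if (is.finite(disp)) {
          stats::rnbinom(1, size = disp, mu = cfg$focus_count_mean[cat_j])
        } else {
          rpois(1, cfg$focus_count_mean[cat_j])
        }
        min_sep <- cfg$separation_factor * cfg$focus_sigma_um[cat_j]
        ctr <- sample_focus_centres(nuc, n_foci, min_sep, cfg)
        n_placed <- nrow(ctr)
        if (n_placed > 0) {
          zc <- if (cfg$n_slices > 1) {
            runif(n_placed, 1.5, cfg$n_slices - 0.5)
          } else {
            rep(1, n_placed)
          }
          sig <- cfg$focus_sigma_um[cat_j] * rlnorm_cv(n_placed, cfg$focus_sigma_cv)
          pk <- cfg$focus_peak[cat_j] * rlnorm_cv(n_placed, cfg$focus_peak_cv)
          field_foci[[j]] <- tibble::tibble(
            field = f, nucleus_id = j,
            x_px = ctr[, 1] / ps - 0.5, y_px = ctr[, 2] / ps - 0.5,
            z = zc, sigma_um = sig, peak = pk
          )
        }
        nuc_tbl[[length(nuc_tbl) + 1L]] <- tibble::tibble(
          field = f, nucleus_id = j, category = cat_j,
          cx_um = nuc$cx, cy_um = nuc$cy, a_um = nuc$a, b_um = nuc$b,
          theta = nuc$theta, edu_level = edu_level, n_foci = n_placed
        )
      }
      ff <- dplyr::bind_rows(field_foci)

      edu <- array(0, dim = c(h, w, cfg$n_slices))
      rad <- array(0, dim = c(h, w, cfg$n_slices))
      for (z in seq_len(cfg$n_slices)) {
        rad_slice <- rad_base
        if (nrow(ff) > 0) {
          for (k in seq_len(nrow(ff))) {
            zfac <- exp(-((z - ff$z[k])^2) / (2 * (cfg$focus_sigma_z_um)^2))
            if (zfac < 1e-3) next
            s_px <- ff$sigma_um[k] / ps
            half <- ceiling(3.5 * s_px)
            c0 <- round(ff$x_px[k]) + 1L
            r0 <- round(ff$y_px[k]) + 1L
            cols <- max(1L, c0 - half):min(w, c0 + half)
            rows <- max(1L, r0 - half):min(h, r0 + half)
            dx2 <- outer(rep(1, length(rows)), (cols - 1L - ff$x_px[k])^2)
            dy2 <- outer((rows - 1L - ff$y_px[k])^2, rep(1, length(cols)))
            rad_slice[rows, cols] <- rad_slice[rows, cols] +
              ff$peak[k] * zfac * exp(-(dx2 + dy2) / (2 * s_px^2))
          }
        }
        edu[, , z] <- apply_camera_noise(edu_sig, cfg)
        rad[, , z] <- apply_camera_noise(rad_slice, cfg)
      }
      fields[[f]] <- list(edu = edu, rad51 = rad)
      masks[[f]] <- labels
      foci_tbl[[f]] <- ff
    })
  }
  structure(
    list(
      fields = fields,
      nuclei = dplyr::bind_rows(nuc_tbl),
      foci = dplyr::bind_rows(foci_tbl),
      masks = masks,
      config = cfg
    ),
    class = "image_dataset"
  )
}

#' Write an image dataset to disk as TIFF + CSV
#'
#' Each field is written as a channel-major multi-page 16-bit TIFF (all EdU
#' slices, then all RAD51 slices), the nucleus label mask as a 16-bit TIFF,
#' and the ground-truth nucleus and focus tables as CSV.
#'
#' @param ds an `image_dataset` from [gen_image_dataset()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_image_dataset <- function(ds, dir) {
  stopifnot(inherits(ds, "image_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (f in seq_along(ds$fields)) {
    fld <- ds$fields[[f]]
    pages <- c(asplit(fld$edu, 3L), asplit(fld$rad51, 3L))
    pages <- lapply(pages, function(m) matrix(m, nrow(m)) / 65535)
    tiff::writeTIFF(pages, file.path(dir, sprintf("field_%03d.tif", f)),
                    bits.per.sample = 16L)
    tiff::writeTIFF(ds$masks[[f]] / 65535,
                    file.path(dir, sprintf("field_%03d_mask.tif", f)),
                    bits.per.sample = 16L)
  }
  readr::write_csv(ds$nuclei, file.path(dir, "truth_nuclei.csv"))
  readr::write_csv(ds$foci, file.path(dir, "truth_foci.csv"))
  invisible(dir)
}

#' Read a channel-major multi-page TIFF field back into arrays
#'
#' @param path TIFF file written by [write_image_dataset()].
#' @param n_slices number of Z-slices per channel.
#' @param channels channel names in page order.
#' @return A named list of rows x cols x slices arrays on the original
#'   0-65535 integer scale.
#' @export
read_image_field <- function(path, n_slices, channels = c("edu", "rad51")) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (length(pages) != n_slices * length(channels)) {
    abort(sprintf("expected %d pages, found %d",
                  n_slices * length(channels), length(pages)))
  }
  out <- purrr::imap(channels, function(ch, i) {
    sl <- pages[((i - 1) * n_slices + 1):(i * n_slices)]
    arr <- array(0, dim = c(nrow(sl[[1]]), ncol(sl[[1]]), n_slices))
    for (z in seq_len(n_slices)) arr[, , z] <- round(sl[[z]] * 65535)
    arr
  })
  names(out) <- channels
  out
}
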