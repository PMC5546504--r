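#' Build a pipeline run configuration
#'
#' One structured configuration governs every stage of a reproducible run:
#' synthetic-data generation, focus counting, survival analytics and blot
#' densitometry. The global `seed` deterministically overrides the stage
#' seeds (`seed`, `seed + 1`, `seed + 2`, `seed + 3` for treated images,
#' control images, colony counts and blots), so one integer reproduces the
#' whole run.
#'
#' @param out_dir directory for all run outputs.
#' @param seed global integer seed.
#' @param alpha_level significance level for every shared-vs-separate
#'   decision in the run.
#' @param stages subset of `c("simulate", "foci", "survival", "blot")`.
#' @param image [image_gen_config()] for the treated image fields. The
#'   default uses small fields so that a demo run stays fast.
#' @param image_control [image_gen_config()] for the 37 degC control fields
#'   used as the classification reference; `NULL` derives one from `image`
#'   with a pure category-1 mix.
#' @param survival [survival_gen_config()].
#' @param blot [blot_gen_config()].
#' @param foci_params list of focus-pipeline parameters (see
#'   [analyze_foci()] and [classify_category()]).
#' @return A list of class `run_config`.
#' @export
run_config <- function(out_dir = tempfile("thermhr_run"),
                       seed = 1L,
                       alpha_level = 0.05,
                       stages = c("simulate", "foci", "survival", "blot"),
                       image = image_gen_config(
                         image_width_px = 384L, image_height_px = 384L,
                         n_slices = 5L, n_fields = 7L, nuclei_per_field = 4L
                       ),
                       image_control = NULL,
                       survival = survival_gen_config(),
                       blot = blot_gen_config(),
                       foci_params = list()) {
  stopifnot(alpha_level > 0, alpha_level < 1)
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- as.integer(seed)
  image$seed <- seed
  if (is.null(image_control)) {
    image_control <- image
    image_control$category_mix <- c(1, 0, 0)
  }
  image_control$seed <- seed + 1L
  survival$seed <- seed + 2L
  blot$seed <- seed + 3L
  fp <- utils::modifyList(
    list(min_size_um2 = 0.05, max_size_um2 = 5, min_nucleus_area_um2 = 20,
         edu_positive_k = 3, low_count_q = 0.01, low_density_q = 0.01),
    foci_params
  )
  structure(
    list(out_dir = out_dir, seed = seed, alpha_level = alpha_level,
         stages = stages, image = image, image_control = image_control,
         survival = survival, blot = blot, foci_params = fp),
    class = "run_config"
  )
}

#' Read a run configuration from a YAML file
#'
#' Top-level keys mirror the arguments of [run_config()]; the `image`,
#' `image_control`, `survival` and `blot` sections hold arguments for the
#' corresponding `*_config()` constructors.
#'
#' @param path YAML file.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  for (k in c("out_dir", "seed", "alpha_level", "stages", "foci_params")) {
    if (!is.null(y[[k]])) args[[k]] <- y[[k]]
  }
  if (!is.null(y$image)) args$image <- do.call(image_gen_config, y$image)
  if (!is.null(y$image_control)) {
    args$image_control <- do.call(image_gen_config, y$image_control)
  }
  if (!is.null(y$survival)) args$survival <- do.call(survival_gen_config, y$survival)
  if (!is.null(y$blot)) args$blot <- do.call(blot_gen_config, y$blot)
  do.call(run_config, args)
}

#' Execute the full analysis pipeline
#'
#' Runs the enabled stages in order — synthetic-data generation, focus
#' counting (treated fields classified against the control reference),
#' survival analytics (plating efficiency, surviving fractions,
#' linear-quadratic fits and shared-vs-separate comparisons per
#' temperature) and blot densitometry (normalization and ANOVA/Tukey per
#' temperature) — writing all tables under `cfg$out_dir`. Identical
#' configuration and seed give identical numeric outputs.
#'
#' @param cfg a [run_config()].
#' @param write_images also write the synthetic TIFF stacks (default FALSE;
#'   the in-memory arrays are analysed either way).
#' @return A list of class `run_report`: per-stage summary tables, the
#'   package version, the configuration hash and wall-clock metadata.
#' @export
run_pipeline <- function(cfg = run_config(), write_images = FALSE) {
  stopifnot(inherits(cfg, "run_config"))
  t0 <- Sys.time()
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  report <- list()
  fp <- cfg$foci_params

  imgs <- NULL; imgs_ctrl <- NULL; colonies <- NULL; bands <- NULL
  if ("simulate" %in% cfg$stages) {
    imgs <- gen_image_dataset(cfg$image)
    imgs_ctrl <- gen_image_dataset(cfg$image_control)
    colonies <- gen_colony_counts(cfg$survival)
    bands <- gen_blot_table(cfg$blot)
    readr::write_csv(colonies, file.path(cfg$out_dir, "colony_counts.csv"))
    readr::write_csv(bands, file.path(cfg$out_dir, "blot_bands.csv"))
    if (write_images) {
      write_image_dataset(imgs, file.path(cfg$out_dir, "images_treated"))
      write_image_dataset(imgs_ctrl, file.path(cfg$out_dir, "images_control"))
    }
    report$simulate <- tibble::tibble(
      table = c("colony_counts", "blot_bands", "nuclei_treated", "nuclei_control"),
      rows = c(nrow(colonies), nrow(bands), nrow(imgs$nuclei),
               nrow(imgs_ctrl$nuclei))
    )
  }

  if ("foci" %in% cfg$stages) {
    if (is.null(imgs)) abort("foci stage requires the simulate stage")
    an_t <- analyze_foci(imgs, min_size_um2 = fp$min_size_um2,
                         max_size_um2 = fp$max_size_um2,
                         min_nucleus_area_um2 = fp$min_nucleus_area_um2,
                         edu_positive_k = fp$edu_positive_k)
    an_c <- analyze_foci(imgs_ctrl, min_size_um2 = fp$min_size_um2,
                         max_size_um2 = fp$max_size_um2,
                         min_nucleus_area_um2 = fp$min_nucleus_area_um2,
                         edu_positive_k = fp$edu_positive_k)
    classified <- classify_category(an_t$profiles, an_c$profiles,
                                    low_count_q = fp$low_count_q,
                                    low_density_q = fp$low_density_q)
    readr::write_csv(classified, file.path(cfg$out_dir, "nucleus_profiles.csv"))
    readr::write_csv(an_c$profiles, file.path(cfg$out_dir, "control_profiles.csv"))
    report$foci <- classified |>
      dplyr::count(.data$category, name = "n_nuclei")
  }

  if ("survival" %in% cfg$stages) {
    if (is.null(colonies)) abort("survival stage requires the simulate stage")
    pe <- plating_efficiency(colonies)
    sf <- surviving_fraction(colonies)
    readr::write_csv(pe, file.path(cfg$out_dir, "plating_efficiency.csv"))
    readr::write_csv(sf, file.path(cfg$out_dir, "surviving_fraction.csv"))
    fits <- sf |>
      dplyr::group_by(.data$temperature_C, .data$duration_min) |>
      dplyr::group_modify(function(d, key) {
        fit <- fit_lq(d)
        tibble::tibble(alpha = fit$alpha, beta = fit$beta, rss = fit$rss,
                       df = fit$df, n_points = fit$n_points)
      }) |>
      dplyr::ungroup()
    readr::write_csv(fits, file.path(cfg$out_dir, "lq_fits.csv"))
    cmps <- sf |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::group_modify(function(d, key) {
        if (dplyr::n_distinct(d$duration_min) < 2L) return(tibble::tibble())
        cmp <- compare_curves(d, group = "duration_min", x = "dose_Gy",
                              y = "sf", model = "lq",
                              alpha_level = cfg$alpha_level)
        tibble::tibble(F = cmp$F, df_num = cmp$df_num, df_den = cmp$df_den,
                       p = cmp$p, shared_curve = cmp$shared_curve)
      }) |>
      dplyr::ungroup()
    readr::write_csv(cmps, file.path(cfg$out_dir, "curve_comparisons.csv"))
    jsonlite::write_json(cmps, file.path(cfg$out_dir, "curve_comparisons.json"),
                         dataframe = "rows", digits = NA)
    report$survival <- cmps
  }

  if ("blot" %in% cfg$stages) {
    if (is.null(bands)) abort("blot stage requires the simulate stage")
    levels <- normalize_levels(bands)
    readr::write_csv(levels, file.path(cfg$out_dir, "blot_levels.csv"))
    stats_by_temp <- levels |>
      dplyr::group_by(.data$temperature_C) |>
      dplyr::group_modify(function(d, key) {
        anova_tukey(d, value = "level", group = "duration_min",
                    alpha_level = cfg$alpha_level)$anova
      }) |>
      dplyr::ungroup()
    readr::write_csv(stats_by_temp, file.path(cfg$out_dir, "blot_anova.csv"))
    jsonlite::write_json(stats_by_temp, file.path(cfg$out_dir, "blot_anova.json"),
                         dataframe = "rows", digits = NA)
    summary_lv <- levels |>
      dplyr::group_by(.data$temperature_C, .data$duration_min) |>
      dplyr::summarise(mean_level = mean(.data$level),
                       sem = sd(.data$level) / sqrt(dplyr::n()),
                       n = dplyr::n(), .groups = "drop")
    readr::write_csv(summary_lv, file.path(cfg$out_dir, "blot_level_summary.csv"))
    report$blot <- summary_lv
  }

  structure(
    list(
      stages = report,
      config_hash = rlang::hash(cfg[setdiff(names(cfg), "out_dir")]),
      version = as.character(utils::packageVersion("thermhr")),
      started = t0,
      elapsed_s = as.numeric(difftime(Sys.time(), t0, units = "secs")),
      out_dir = cfg$out_dir
    ),
    class = "run_report"
  )
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("thermhr %s pipeline run (config %s, %.1f s)\nOutputs: %s\n",
              x$version, x$config_hash, x$elapsed_s, x$out_dir))
  for (nm in names(x$stages)) {
    cat("\n--", nm, "--\n")
    print(x$stages[[nm]])
  }
  invisible(x)
}
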