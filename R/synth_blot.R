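#' Default BRCA2 thermal-dose response profile
#'
#' The ground-truth relative BRCA2 level (fraction of the 37 degC control)
#' assumed by the synthetic blot generator for every thermal dose in
#' [thermal_design()]. The profile is anchored at the landmark values of the
#' whole-cell-extract dose response: the strongest depletion (22% of control)
#' at 43 degC / 60 min, 64% remaining after 240 min at 40 degC, and roughly
#' 60% remaining after 60 min at 41 degC; the remaining grid points
#' interpolate those anchors with the depletion saturating — and partially
#' reverting to insoluble, still-detectable protein — above 43 degC.
#' Every 0-minute arm is exactly 1 (it is the 37 degC control).
#'
#' @return A tibble with columns `temperature_C`, `duration_min`,
#'   `rel_level` (fraction of control in `[0, 1]`).
#' @export
default_brca2_profile <- function() {
  prof <- thermal_design()
  lvl <- c(
    1.00, 0.85, 0.75, 0.64,   # 40 C
    1.00, 0.60, 0.45, 0.38,   # 41 C
    1.00, 0.55, 0.30, 0.26,   # 42 C
    1.00, 0.55, 0.35, 0.22,   # 43 C
    1.00, 0.60, 0.42, 0.28,   # 43.5 C
    1.00, 0.65, 0.48, 0.32    # 44 C
  )
  prof$rel_level <- lvl
  prof
}

#' Configuration for the synthetic immunoblot generator
#'
#' @param profile tibble with columns `temperature_C`, `duration_min`,
#'   `rel_level`: the true relative target-protein level per condition as a
#'   fraction of the 37 degC control. Defaults to [default_brca2_profile()].
#' @param control_level loading-control band signal per lane (a.u.).
#' @param cv multiplicative noise coefficient of variation on the target band
#'   signal (lognormal, mean 1).
#' @param replicates number of replicates per condition (one per cell line in
#'   the default design).
#' @param cell_lines labels for the replicates; length must equal
#'   `replicates`.
#' @param fraction lysate fraction label attached to every row.
#' @param seed integer seed; identical seeds give bit-identical tables.
#' @return A list of class `blot_gen_config`.
#' @export
blot_gen_config <- function(profile = default_brca2_profile(),
                            control_level = 10000,
                            cv = 0.15,
                            replicates = 4L,
                            cell_lines = c("BLM", "HeLa", "FaDu", "VH10-SV40"),
                            fraction = "whole",
                            seed = 1L) {
  stopifnot(
    is.data.frame(profile),
    all(c("temperature_C", "duration_min", "rel_level") %in% names(profile)),
    all(profile$rel_level >= 0)
  )
  check_scalar_number(control_level, "control_level", lower = 0)
  check_scalar_number(cv, "cv", lower = 0)
  check_scalar_number(replicates, "replicates", lower = 1)
  check_scalar_number(seed, "seed")
  if (length(cell_lines) != replicates) {
    cell_lines <- paste0("line", seq_len(replicates))
  }
  structure(
    list(
      profile = tibble::as_tibble(profile),
      control_level = control_level,
      cv = cv,
      replicates = as.integer(replicates),
      cell_lines = cell_lines,
      fraction = fraction,
      seed = as.integer(seed)
    ),
    class = "blot_gen_config"
  )
}

#' Generate a synthetic immunoblot band-signal table
#'
#' Emulates densitometry of one blot per temperature: each blot carries one
#' lane per (cell line, duration) with a target band and a loading-control
#' band. The target signal is `control_level * rel_level * noise` with
#' mean-one lognormal noise of coefficient of variation `cv`; the
#' loading-control signal is noise-free so that, with `cv = 0`, the pipeline
#' recovers the configured truth exactly.
#'
#' @param cfg a [blot_gen_config()].
#' @return A tibble of band measurements with columns `experiment`,
#'   `cell_line`, `temperature_C`, `duration_min`, `fraction`,
#'   `target_signal`, `control_signal`, `true_rel_level`.
#' @examples
#' gen_blot_table(blot_gen_config(cv = 0, replicates = 2))
#' @export
gen_blot_table <- function(cfg = blot_gen_config()) {
  stopifnot(inherits(cfg, "blot_gen_config"))
  with_seed(cfg$seed, {
    tbl <- tidyr::crossing(cell_line = cfg$cell_lines, cfg$profile) |>
      dplyr::arrange(.data$temperature_C, .data$duration_min, .data$cell_line) |>
      dplyr::mutate(
        experiment = paste0("T", .data$temperature_C),
        fraction = cfg$fraction,
        control_signal = cfg$control_level,
        target_signal = .data$control_signal * .data$rel_level *
          rlnorm_cv(dplyr::n(), cfg$cv)
      )
  })
  tbl |>
    dplyr::transmute(
      experiment = .data$experiment,
      cell_line = .data$cell_line,
      temperature_C = .data$temperature_C,
      duration_min = .data$duration_min,
      fraction = .data$fraction,
      target_signal = .data$target_signal,
      control_signal = .data$control_signal,
      true_rel_level = .data$rel_level
    )
}
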