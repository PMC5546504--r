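#' Default heat-kill plating-efficiency profile
#'
#' Multiplier applied to the 37 degC plating efficiency for each thermal
#' dose in the synthetic clonogenic generator. Plating efficiency declines
#' approximately linearly with treatment duration, with a steeper slope at
#' higher temperature; 40 degC barely affects plating while 44 degC for
#' 60 min removes about a third of the colony-forming cells.
#'
#' @return A tibble with columns `temperature_C`, `duration_min`, `pe_mult`
#'   (multiplier in `(0, 1]`, exactly 1 on every 0-minute arm).
#' @export
default_pe_profile <- function() {
  slopes <- c(`40` = 0.0003, `41` = 0.0008, `42` = 0.002,
              `43` = 0.004, `43.5` = 0.005, `44` = 0.006)
  thermal_design() |>
    dplyr::mutate(
      pe_mult = pmax(0.05, 1 - slopes[as.character(.data$temperature_C)] *
                       .data$duration_min)
    )
}

#' Configuration for the synthetic clonogenic-survival generator
#'
#' @param design tibble of thermal doses (`temperature_C`, `duration_min`);
#'   defaults to the full [thermal_design()] grid.
#' @param doses_Gy radiation doses applied within each thermal dose.
#' @param alpha,beta true linear-quadratic parameters. Either scalars (shared
#'   by all conditions) or tibbles with columns `temperature_C`,
#'   `duration_min` and `alpha`/`beta` for condition-specific truth.
#' @param pe_37 plating efficiency of unheated cells, in `(0, 1]`.
#' @param pe_profile tibble mapping each thermal dose to its heat-kill
#'   plating-efficiency multiplier (column `pe_mult`); defaults to
#'   [default_pe_profile()].
#' @param base_seeded cells seeded at 0 Gy (scalar, or named vector per cell
#'   line as in [clonogenic_defaults()]).
#' @param doubling_per_Gy Gy step per doubling of seeded cells.
#' @param cell_lines cell-line labels.
#' @param replicates plates per (cell line, thermal dose, radiation dose).
#' @param seed integer seed.
#' @return A list of class `survival_gen_config`.
#' @export
survival_gen_config <- function(design = thermal_design(),
                                doses_Gy = c(0, 2, 4, 6),
                                alpha = 0.3,
                                beta = 0.03,
                                pe_37 = 0.7,
                                pe_profile = default_pe_profile(),
                                base_seeded = 200,
                                doubling_per_Gy = 2,
                                cell_lines = "HeLa",
                                replicates = 3L,
                                seed = 1L) {
  stopifnot(
    is.data.frame(design),
    all(c("temperature_C", "duration_min") %in% names(design)),
    all(doses_Gy >= 0)
  )
  if (is.numeric(alpha)) check_scalar_number(alpha, "alpha", lower = 0)
  if (is.numeric(beta)) check_scalar_number(beta, "beta", lower = 0)
  check_scalar_number(pe_37, "pe_37", lower = 1e-12, upper = 1)
  stopifnot(all(pe_profile$pe_mult > 0), all(pe_profile$pe_mult <= 1))
  structure(
    list(
      design = tibble::as_tibble(design),
      doses_Gy = doses_Gy,
      alpha = alpha, beta = beta,
      pe_37 = pe_37,
      pe_profile = tibble::as_tibble(pe_profile),
      base_seeded = base_seeded,
      doubling_per_Gy = doubling_per_Gy,
      cell_lines = cell_lines,
      replicates = as.integer(replicates),
      seed = as.integer(seed)
    ),
    class = "survival_gen_config"
  )
}

resolve_lq_truth <- function(cfg) {
  truth <- cfg$design
  if (is.data.frame(cfg$alpha)) {
    truth <- dplyr::left_join(truth, cfg$alpha,
                              by = c("temperature_C", "duration_min"))
  } else {
    truth$alpha <- cfg$alpha
  }
  if (is.data.frame(cfg$beta)) {
    truth <- dplyr::left_join(truth, cfg$beta,
                              by = c("temperature_C", "duration_min"))
  } else {
    truth$beta <- cfg$beta
  }
  stopifnot(!anyNA(truth$alpha), !anyNA(truth$beta))
  truth
}

#' Generate synthetic clonogenic colony counts
#'
#' Simulates one clonogenic plate per row of the expanded design: colonies
#' are drawn as Poisson with mean
#' `seeded * PE(condition) * exp(-(alpha * D + beta * D^2))`, where
#' `PE(condition) = pe_37 * pe_mult` reflects direct heat kill and the
#' exponential factor is the linear-quadratic radiation survival law.
#' Seeded cell numbers follow the dose-doubling rule of
#' [seeded_at_dose()].
#'
#' @param cfg a [survival_gen_config()].
#' @return A tibble of survival observations with columns `cell_line`,
#'   `temperature_C`, `duration_min`, `dose_Gy`, `replicate`, `seeded`,
#'   `colonies`, plus the ground-truth columns `true_alpha`, `true_beta`,
#'   `true_pe`.
#' @examples
#' gen_colony_counts(survival_gen_config(replicates = 1))
#' @export
gen_colony_counts <- function(cfg = survival_gen_config()) {
  stopifnot(inherits(cfg, "survival_gen_config"))
  truth <- resolve_lq_truth(cfg)
  truth <- dplyr::left_join(truth, cfg$pe_profile,
                            by = c("temperature_C", "duration_min"))
  stopifnot(!anyNA(truth$pe_mult))

  seeded_for <- function(line, dose) {
    base <- if (length(cfg$base_seeded) > 1L) {
      unname(cfg$base_seeded[line])
    } else {
      cfg$base_seeded
    }
    seeded_at_dose(base, dose, cfg$doubling_per_Gy)
  }

  grid <- tidyr::crossing(
    cell_line = cfg$cell_lines,
    truth,
    dose_Gy = cfg$doses_Gy,
    replicate = seq_len(cfg$replicates)
  )
  with_seed(cfg$seed, {
    grid <- grid |>
      dplyr::mutate(
        seeded = seeded_for(.data$cell_line, .data$dose_Gy),
        true_pe = cfg$pe_37 * .data$pe_mult,
        sf = exp(-(.data$alpha * .data$dose_Gy +
                     .data$beta * .data$dose_Gy^2)),
        colonies = rpois(dplyr::n(), .data$seeded * .data$true_pe * .data$sf)
      )
  })
  grid |>
    dplyr::transmute(
      cell_line = .data$cell_line,
      temperature_C = .data$temperature_C,
      duration_min = .data$duration_min,
      dose_Gy = .data$dose_Gy,
      replicate = .data$replicate,
      seeded = .data$seeded,
      colonies = as.integer(.data$colonies),
      true_alpha = .data$alpha,
      true_beta = .data$beta,
      true_pe = .data$true_pe
    )
}
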