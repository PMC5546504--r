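#' Thermal-dose design grid
#'
#' The treatment design used throughout the package: six hyperthermia
#' temperatures, each with four treatment durations (the 0-minute arm of every
#' temperature is the 37 degC control). Lower temperatures are applied for
#' longer, so the grid spans comparable thermal doses.
#'
#' @return A tibble with columns `temperature_C` (numeric) and `duration_min`
#'   (numeric), one row per thermal dose, including the 0-minute control arm
#'   of each temperature.
#' @examples
#' thermal_design()
#' @export
thermal_design <- function() {
  tibble::tibble(
    temperature_C = rep(c(40, 41, 42, 43, 43.5, 44), each = 4L),
    duration_min = c(
      0, 60, 120, 240,
      0, 60, 120, 240,
      0, 30, 60, 120,
      0, 15, 30, 60,
      0, 15, 30, 60,
      0, 15, 30, 60
    )
  )
}

#' Clonogenic assay design defaults
#'
#' Default seeding and scoring rules for the clonogenic survival assay:
#' how many cells are plated at 0 Gy for each cell line, how seeding scales
#' with radiation dose, and the minimum colony size that is scored.
#'
#' @return A list with elements:
#'   \describe{
#'     \item{seeded_0Gy}{named numeric vector of cells seeded at 0 Gy per
#'       cell line (fast-growing lines 200, slower lines 300).}
#'     \item{doubling_per_Gy}{seeded cells are doubled for every this many Gy
#'       of irradiation (2 Gy), so seeded(D) = seeded(0) * 2^(D / 2).}
#'     \item{min_colony_cells}{colonies must contain more than this many cells
#'       (30) to be counted.}
#'   }
#' @export
clonogenic_defaults <- function() {
  list(
    seeded_0Gy = c(BLM = 200, HeLa = 200, FaDu = 300, `VH10-SV40` = 300),
    doubling_per_Gy = 2,
    min_colony_cells = 30L
  )
}

#' Number of cells seeded at each radiation dose
#'
#' Applies the dose-dependent seeding rule: the number of cells plated is
#' doubled for each `doubling_per_Gy` Gy increase in radiation dose, so that
#' heavily irradiated plates still yield countable colonies.
#'
#' @param base_seeded cells seeded at 0 Gy.
#' @param dose_Gy radiation dose(s) in Gy.
#' @param doubling_per_Gy dose step (Gy) per doubling of seeded cells.
#' @return Integer vector of seeded cell counts.
#' @export
seeded_at_dose <- function(base_seeded, dose_Gy, doubling_per_Gy = 2) {
  stopifnot(base_seeded > 0, all(dose_Gy >= 0), doubling_per_Gy > 0)
  as.integer(round(base_seeded * 2^(dose_Gy / doubling_per_Gy)))
}
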