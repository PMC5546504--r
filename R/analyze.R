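#' Run the full focus-counting pipeline on an image dataset
#'
#' For every field: maximum-project both channels, segment EdU-stained
#' nuclei, gate on EdU positivity, threshold RAD51 within each nucleus with
#' the maximum-entropy algorithm, run particle analysis with the configured
#' size bounds, and summarize per-nucleus focus statistics.
#'
#' @param ds an `image_dataset` from [gen_image_dataset()], or a list of
#'   fields (each `list(edu = , rad51 = )` arrays).
#' @param pixel_size_um pixel size; taken from `ds$config` when available.
#' @param min_size_um2,max_size_um2 focus size bounds (square micrometres).
#' @param min_nucleus_area_um2 minimum nucleus area.
#' @param edu_threshold optional fixed EdU segmentation threshold.
#' @param edu_positive_k EdU positivity cutoff in background SD units.
#' @param edu_positive_only analyse only EdU-positive nuclei (default TRUE;
#'   S-phase cells are the ones competent for recombination).
#' @param max_gray full-scale gray value.
#' @return An object of class `foci_analysis`: `profiles` (per-nucleus
#'   tibble with `field` column), `foci` (per-focus tibble), `rois`
#'   (per-nucleus segmentation tibble).
#' @export
analyze_foci <- function(ds, pixel_size_um = NULL,
                         min_size_um2 = 0.05, max_size_um2 = 5,
                         min_nucleus_area_um2 = 20,
                         edu_threshold = NULL, edu_positive_k = 3,
                         edu_positive_only = TRUE, max_gray = 65535) {
  fields <- if (inherits(ds, "image_dataset")) ds$fields else ds
  if (is.null(pixel_size_um) && inherits(ds, "image_dataset")) {
    pixel_size_um <- ds$config$pixel_size_um
  }
  stopifnot(!is.null(pixel_size_um))
  res <- purrr::imap(fields, function(fld, f) {
    edu <- max_project(fld$edu)
    rad <- max_project(fld$rad51)
    rois <- segment_edu_nuclei(edu, pixel_size_um,
                               threshold = edu_threshold,
                               min_area_um2 = min_nucleus_area_um2,
                               edu_positive_k = edu_positive_k,
                               max_gray = max_gray)
    use <- if (edu_positive_only) {
      dplyr::filter(rois, .data$edu_positive)
    } else {
      rois
    }
    foci <- purrr::map_dfr(seq_len(nrow(use)), function(i) {
      fc <- detect_foci(rad, use$pixels[[i]], pixel_size_um,
                        min_size_um2 = min_size_um2,
                        max_size_um2 = max_size_um2, max_gray = max_gray)
      if (nrow(fc) == 0L) return(NULL)
      dplyr::mutate(fc, nucleus_id = use$nucleus_id[i], .before = 1L)
    })
    prof <- profile_nuclei(foci, use)
    list(
      rois = dplyr::mutate(dplyr::select(rois, -"pixels"), field = f, .before = 1L),
      foci = if (nrow(foci)) dplyr::mutate(foci, field = f, .before = 1L) else foci,
      profiles = dplyr::mutate(prof, field = f, .before = 1L)
    )
  })
  structure(
    list(
      profiles = purrr::map_dfr(res, "profiles"),
      foci = purrr::map_dfr(res, "foci"),
      rois = purrr::map_dfr(res, "rois")
    ),
    class = "foci_analysis"
  )
}

#' @export
print.foci_analysis <- function(x, ...) {
  cat(sprintf("Focus analysis: %d nuclei, %d foci in %d field(s)\n",
              nrow(x$profiles), nrow(x$foci),
              dplyr::n_distinct(x$profiles$field)))
  print(x$profiles)
  invisible(x)
}

#' Match detected nuclei to ground-truth nuclei by centroid
#'
#' Assigns each segmented nucleus the nearest planted nucleus (within half a
#' nucleus radius), for evaluating the pipeline against generator truth.
#'
#' @param profiles per-nucleus tibble from [analyze_foci()] (needs `field`,
#'   `nucleus_id`); the matching uses the segmentation centroids in
#'   `rois`.
#' @param rois segmentation tibble from [analyze_foci()].
#' @param truth ground-truth nucleus tibble from [gen_image_dataset()].
#' @param pixel_size_um pixel size.
#' @return `profiles` with `true_category`, `true_n_foci`, `true_edu_level`
#'   appended (`NA` when unmatched).
#' @export
match_truth <- function(profiles, rois, truth, pixel_size_um) {
  ctr <- dplyr::select(rois, "field", "nucleus_id", "cx", "cy")
  out <- dplyr::left_join(profiles, ctr, by = c("field", "nucleus_id"))
  idx <- purrr::pmap_int(
    list(out$field, out$cx, out$cy),
    function(f, cx, cy) {
      tr <- which(truth$field == f)
      if (!length(tr)) return(NA_integer_)
      d <- sqrt((truth$cx_um[tr] - (cx + 0.5) * pixel_size_um)^2 +
                  (truth$cy_um[tr] - (cy + 0.5) * pixel_size_um)^2)
      j <- which.min(d)
      if (d[j] <= truth$a_um[tr[j]]) tr[j] else NA_integer_
    }
  )
  out$true_category <- truth$category[idx]
  out$true_n_foci <- truth$n_foci[idx]
  out$true_edu_level <- truth$edu_level[idx]
  dplyr::select(out, -"cx", -"cy")
}
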