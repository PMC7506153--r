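#' Convert an activity-concentration volume to SUV
#'
#' Standardised uptake value: tissue activity concentration normalised by
#' injected dose per body weight, `SUV = C[kBq/mL] * weight[kg] /
#' dose[MBq]` (unit-consistent assuming 1 g/mL tissue density). Volumes that
#' are already in SUV units pass through unchanged when `already_suv = TRUE`.
#'
#' @param activity A `voxel_grid` of activity concentration in kBq/mL.
#' @param injected_dose_MBq Injected dose (MBq), > 0.
#' @param body_weight_kg Body weight (kg), > 0.
#' @param already_suv Flag for volumes already expressed in SUV.
#' @return A `voxel_grid` in SUV units.
#' @examples
#' g <- voxel_grid(array(37, c(2, 2, 2)))
#' max(compute_suv(g, injected_dose_MBq = 259, body_weight_kg = 70)$values)  # 10
#' @export
compute_suv <- function(activity, injected_dose_MBq, body_weight_kg,
                        already_suv = FALSE) {
  if (already_suv) return(activity)
  if (!is.finite(injected_dose_MBq) || injected_dose_MBq <= 0) {
    abort("`injected_dose_MBq` must be positive.")
  }
  if (!is.finite(body_weight_kg) || body_weight_kg <= 0) {
    abort("`body_weight_kg` must be positive.")
  }
  voxel_grid(activity$values * body_weight_kg / injected_dose_MBq,
             spacing_mm = activity$spacing_mm, origin_mm = activity$origin_mm)
}

#' Delineate the metabolic ROI at a fraction of SUVmax
#'
#' Adaptive-threshold segmentation of the metabolically active tumour: SUVmax
#' is taken within a seed box, voxels in the box at or above
#' `threshold_fraction * SUVmax` are selected, and the result is restricted to
#' the 26-connected component containing the maximum voxel (a reproducible
#' stand-in for the operator's manual exclusion of nearby hot normal tissue).
#'
#' @param suv A `voxel_grid` in SUV units (not grey-normalised).
#' @param box Seed box: list with `lo`, `hi` (1-based inclusive voxel
#'   indices), e.g. from [seed_box_from_mask()].
#' @param threshold_fraction Relative threshold, default 0.40.
#' @return An `roi_mask` (the metabolic mask).
#' @export
delineate_metabolic_roi <- function(suv, box, threshold_fraction = 0.40) {
  stopifnot(is.list(box), all(box$lo >= 1), all(box$hi <= dim(suv$values)),
            all(box$lo <= box$hi))
  if (!(threshold_fraction > 0 && threshold_fraction <= 1)) {
    abort("`threshold_fraction` must be in (0, 1].")
  }
  sub <- suv$values[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3],
                    drop = FALSE]
  mx <- max(sub)
  if (mx == min(sub)) abort("flat seed box: no contrast to threshold.")
  thr <- threshold_fraction * mx
  above <- sub >= thr
  comp <- flood_fill26(above, which.max(sub))
  full <- array(FALSE, dim(suv$values))
  full[box$lo[1]:box$hi[1], box$lo[2]:box$hi[2], box$lo[3]:box$hi[3]] <- comp
  roi_mask(full, spacing_mm = suv$spacing_mm, origin_mm = suv$origin_mm)
}

#' @param mask The anatomical lesion mask.
#' @param margin Dilation of the bounding box in voxels, default 3.
#' @rdname delineate_metabolic_roi
#' @export
seed_box_from_mask <- function(mask, margin = 3L) {
  mask_bbox(mask, margin = margin)
}

#' Per-lesion metabolic summary
#'
#' SUVmax and SUVmean over the metabolic mask, metabolic tumour volume
#' `MTV = voxel count x voxel volume` (mL) and total lesion glycolysis
#' `TLG = SUVmean x MTV`.
#'
#' @param suv A `voxel_grid` in SUV units.
#' @param mask An aligned `roi_mask` (normally the 40%-of-SUVmax mask).
#' @return A one-row tibble: `suv_max`, `suv_mean`, `mtv_ml`, `tlg`.
#' @export
metabolic_summary <- function(suv, mask) {
  check_aligned(suv, mask)
  x <- suv$values[mask$values]
  if (length(x) == 0L) abort("empty metabolic mask.")
  mtv <- length(x) * prod(suv$spacing_mm) / 1000  # mm^3 -> mL
  tibble(
    suv_max = max(x),
    suv_mean = mean(x),
    mtv_ml = mtv,
    tlg = mean(x) * mtv
  )
}

#' Metabolic parameters for a whole cohort
#'
#' For each subject: seed box = anatomical mask bounding box dilated by 3
#' voxels, metabolic ROI at `threshold_fraction` of box SUVmax, then the
#' SUVmax / SUVmean / MTV / TLG summary. Computed on the un-normalised SUV
#' volume (texture features use the grey-normalised one).
#'
#' @param cohort A `radstage_cohort`.
#' @param threshold_fraction Relative SUV threshold, default 0.40.
#' @return A tibble: `subject_id`, `suv_max`, `suv_mean`, `mtv_ml`, `tlg`.
#' @export
cohort_metabolics <- function(cohort, threshold_fraction = 0.40) {
  rows <- purrr::map(cohort$subjects, function(s) {
    box <- seed_box_from_mask(s$lesion_mask, margin = 3L)
    roi <- delineate_metabolic_roi(s$pet_volume, box, threshold_fraction)
    dplyr::bind_cols(tibble(subject_id = s$subject_id),
                     metabolic_summary(s$pet_volume, roi))
  })
  dplyr::bind_rows(rows)
}
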