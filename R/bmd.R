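#' Calibration reference pair for phantom-less BMD
#'
#' In-body calibrated quantitative CT maps trabecular HU to mineral
#' density through two internal reference tissues: subcutaneous fat and
#' paravertebral (erector spinae) muscle. Each reference tissue is
#' assigned a hydroxyapatite-equivalent density; the two measured ROI
#' means then anchor an affine HU-to-mg/ml map.
#'
#' The default equivalent densities are derived from the material basis so
#' that the two-point line inverts the marrow mixing line (mineral
#' displacing fat over a mostly-fatty baseline); see
#' [default_calibration_pair()].
#'
#' @param hu_fat_ref,hu_muscle_ref Nominal HU of the reference tissues
#'   (used for validation; the measured ROI means anchor the map).
#' @param density_fat_equiv,density_muscle_equiv Assigned equivalent
#'   densities, mg/ml.
#' @return An object of class `calibration_pair`.
#' @export
calibration_pair <- function(hu_fat_ref = -100, hu_muscle_ref = 45,
                             density_fat_equiv = -2.636364,
                             density_muscle_equiv = 50.090909) {
  if (hu_muscle_ref <= hu_fat_ref) stopf("muscle reference HU must exceed fat reference HU")
  if (density_muscle_equiv == density_fat_equiv) stopf("equivalent densities must differ")
  structure(list(hu_fat_ref = hu_fat_ref, hu_muscle_ref = hu_muscle_ref,
                 density_fat_equiv = density_fat_equiv,
                 density_muscle_equiv = density_muscle_equiv),
            class = "calibration_pair")
}

#' Basis-consistent calibration pair
#'
#' Derives the fat and muscle hydroxyapatite-equivalent densities from a
#' [material_basis()] and the baseline marrow soft fraction: trabecular
#' mineral displaces fat over a baseline of
#' `(1 - s0)` fat + `s0` soft tissue, so marrow HU is affine in density
#' with slope `(hu_mineral_conv - hu_fat_conv) / reference_density`.
#' Plugging the pure-tissue HU values into the inverse of that line gives
#' the equivalent densities that make the two-point calibration exact on
#' the marrow line.
#'
#' @param basis A [material_basis()].
#' @param base_soft_fraction Baseline soft-tissue fraction of
#'   uninfiltrated marrow.
#' @return A [calibration_pair()].
#' @export
default_calibration_pair <- function(basis = material_basis(), base_soft_fraction = 0.05) {
  h0 <- (1 - base_soft_fraction) * basis$hu_fat_conv + base_soft_fraction * basis$hu_soft_conv
  k <- basis$reference_mineral_density / (basis$hu_mineral_conv - basis$hu_fat_conv)
  calibration_pair(hu_fat_ref = basis$hu_fat_conv, hu_muscle_ref = basis$hu_soft_conv,
                   density_fat_equiv = k * (basis$hu_fat_conv - h0),
                   density_muscle_equiv = k * (basis$hu_soft_conv - h0))
}

#' Two-point internal calibration
#'
#' Builds the affine HU -> mg/ml map through the two measured reference
#' ROI means. Because both anchors are measured in the same image, a
#' constant scanner-drift offset added to the whole image cancels exactly.
#'
#' @param muscle_roi_mean,fat_roi_mean Measured ROI mean HU values.
#' @param pair A [calibration_pair()] supplying the equivalent densities.
#' @return An object of class `bmd_calibration` (fields `slope`,
#'   `intercept`); apply it with [apply_calibration()].
#' @export
internal_calibration <- function(muscle_roi_mean, fat_roi_mean,
                                 pair = calibration_pair()) {
  if (!is.finite(muscle_roi_mean) || !is.finite(fat_roi_mean)) {
    stopf("reference ROI means must be finite")
  }
  if (muscle_roi_mean <= fat_roi_mean) {
    stopf("degenerate calibration: muscle ROI mean (%.1f HU) must exceed fat ROI mean (%.1f HU)",
          muscle_roi_mean, fat_roi_mean)
  }
  slope <- (pair$density_muscle_equiv - pair$density_fat_equiv) /
    (muscle_roi_mean - fat_roi_mean)
  intercept <- pair$density_fat_equiv - slope * fat_roi_mean
  structure(list(slope = slope, intercept = intercept,
                 fat_roi_mean = fat_roi_mean, muscle_roi_mean = muscle_roi_mean,
                 pair = pair),
            class = "bmd_calibration")
}

#' Apply a BMD calibration map
#'
#' @param cal A `bmd_calibration` from [internal_calibration()].
#' @param hu HU value(s).
#' @return mg/ml value(s).
#' @export
apply_calibration <- function(cal, hu) cal$intercept + cal$slope * hu

#' Trabecular BMD measurement
#'
#' Measures mean conventional HU over the 3-mm-eroded trabecular interiors
#' of the target vertebrae (defaults to the 3rd--5th labels counting from
#' the bottom, i.e. L1--L3 of a thoracolumbar stack whose two lowest
#' labels are L5 and L4) and maps it through the internal calibration. A
#' target vertebra intersecting the lesion/fracture mask is replaced by
#' the next measurable vertebra of the lower spine (caudal fallback), and
#' `fallback_used` is flagged.
#'
#' @param conventional 3-D conventional HU array.
#' @param ls A [labeled_spine()].
#' @param target_labels Labels (positions in the caudal-to-cranial
#'   ordering) to measure; default `3:5`.
#' @param lesion_mask Optional logical array marking lesioned voxels.
#' @param cal A `bmd_calibration`.
#' @param erosion_mm Trabecular ROI erosion depth (default 3 mm, reusing
#'   the cortical erosion operator).
#' @param roi_voxel_keep Fraction of ROI voxels retained (deterministic 1
#'   by default; readers jitter this, see [measure_bmd_readers()]).
#' @param roi_seed Seed for ROI jitter when `roi_voxel_keep < 1`.
#' @return A one-row tibble of class `bmd_result`: `bmd_mg_ml`,
#'   `vertebrae_used` (comma-joined label string), `fallback_used`.
#' @export
measure_bmd <- function(conventional, ls, target_labels = 3:5, lesion_mask = NULL,
                        cal, erosion_mm = 3, roi_voxel_keep = 1, roi_seed = NULL) {
  check_grid3d(conventional, "conventional")
  if (!inherits(ls, "labeled_spine")) stopf("`ls` must be a labeled_spine")
  if (!inherits(cal, "bmd_calibration")) stopf("`cal` must come from internal_calibration()")
  present <- ls$ordering
  idx_of <- function(lab) which(present == lab)
  if (!all(target_labels %in% present)) {
    stopf("target labels (%s) not all present in the spine (%s)",
          paste(target_labels, collapse = ","), paste(present, collapse = ","))
  }
  lesioned <- function(lab) {
    if (is.null(lesion_mask)) return(FALSE)
    any(lesion_mask & ls$label_map == lab)
  }
  # caudal fallback pool: vertebrae below the lowest target, most cranial first
  min_pos <- min(vapply(target_labels, idx_of, 1L))
  pool <- rev(present[seq_len(min_pos - 1)])
  used <- integer(0); fallback <- FALSE
  for (lab in target_labels) {
    if (!lesioned(lab)) {
      used <- c(used, lab)
    } else {
      fallback <- TRUE
      repl <- NA_integer_
      for (cand in pool) {
        if (!cand %in% used && !lesioned(cand)) { repl <- cand; break }
      }
      if (!is.na(repl)) used <- c(used, repl)
    }
  }
  if (length(used) == 0) stopf("no measurable vertebra: all targets lesioned and no caudal fallback")

  vox <- numeric(0)
  for (lab in used) {
    roi <- voi_mask(array(ls$label_map == lab, dim(ls$label_map)), ls$spacing_mm)
    roi <- erode_cortex(roi, erosion_mm)
    v <- conventional[roi$mask]
    if (roi_voxel_keep < 1) {
      if (!is.null(roi_seed)) set.seed(roi_seed + lab)
      v <- v[sample.int(length(v), max(1, round(roi_voxel_keep * length(v))))]
    }
    vox <- c(vox, v)
  }
  if (length(vox) == 0) stopf("no measurable vertebra: trabecular ROI empty after erosion")
  out <- tibble::tibble(bmd_mg_ml = apply_calibration(cal, mean(vox)),
                        vertebrae_used = paste(used, collapse = ","),
                        fallback_used = fallback)
  class(out) <- c("bmd_result", class(out))
  out
}

#' Repeated reader BMD measurements
#'
#' Simulates independent blinded readers by jittering the trabecular ROI:
#' each reader retains a random subset of ROI voxels under a per-reader
#' seed, emulating slightly different ROI placement.
#'
#' @inheritParams measure_bmd
#' @param n_readers Number of readers (default 2).
#' @param keep Fraction of ROI voxels each reader retains.
#' @param seed Base seed; reader r uses `seed + r`.
#' @return Numeric vector of per-reader BMD values, mg/ml.
#' @export
measure_bmd_readers <- function(conventional, ls, target_labels = 3:5,
                                lesion_mask = NULL, cal, erosion_mm = 3,
                                n_readers = 2, keep = 0.6, seed = 1L) {
  vapply(seq_len(n_readers), function(r) {
    rseed <- as.integer((as.numeric(seed) * 131 + r * 1000) %% 2147483629)
    measure_bmd(conventional, ls, target_labels, lesion_mask, cal, erosion_mm,
                roi_voxel_keep = keep, roi_seed = rseed)$bmd_mg_ml
  }, 1.0)
}
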