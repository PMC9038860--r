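#' Read a 3-D HU volume from NIfTI
#'
#' Reads a NIfTI-1 file, reorients it to RAS (so the last array axis runs
#' inferior to superior) when orientation metadata is present, and returns
#' the array with its voxel spacing.
#'
#' @param path NIfTI file path.
#' @return List with `data` (3-D array) and `spacing_mm`.
#' @export
read_hu_volume <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  img <- RNifti::readNifti(path)
  # reorient to RAS when the header carries orientation codes; bare arrays
  # (e.g. phantoms we wrote ourselves) are taken as already RAS
  suppressWarnings(try(RNifti::orientation(img) <- "RAS", silent = TRUE))
  if (length(dim(img)) != 3) {
    stopf("%s: expected a 3-D volume, got %d dimensions", path, length(dim(img)))
  }
  spacing <- RNifti::pixdim(img)[1:3]
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stopf("%s: non-positive voxel spacing in header", path)
  }
  list(data = array(as.numeric(img), dim(img)), spacing_mm = as.numeric(spacing))
}

#' Write a 3-D HU volume to NIfTI
#'
#' @param data 3-D array.
#' @param spacing_mm Voxel spacing, mm.
#' @param path Output path (`.nii` or `.nii.gz`).
#' @return `path`, invisibly.
#' @export
write_hu_volume <- function(data, spacing_mm, path) {
  check_grid3d(data, "data")
  spacing_mm <- check_spacing(spacing_mm)
  img <- RNifti::asNifti(data)
  RNifti::pixdim(img) <- spacing_mm
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

#' Read a dual-energy volume set
#'
#' @param conventional_path,low_path,high_path NIfTI paths of the three
#'   co-registered grids.
#' @return A [spectral_volume()].
#' @export
read_spectral_volume <- function(conventional_path, low_path, high_path) {
  conv <- read_hu_volume(conventional_path)
  low <- read_hu_volume(low_path)
  high <- read_hu_volume(high_path)
  for (other in list(list(low, low_path), list(high, high_path))) {
    if (!identical(dim(conv$data), dim(other[[1]]$data))) {
      stopf("shape mismatch between %s (%s) and %s (%s)",
            conventional_path, paste(dim(conv$data), collapse = "x"),
            other[[2]], paste(dim(other[[1]]$data), collapse = "x"))
    }
  }
  spectral_volume(conv$data, low$data, high$data, conv$spacing_mm)
}

#' Write a phantom's volumes and truth to a directory
#'
#' Writes conventional/low/high HU volumes and the ground-truth label map
#' as NIfTI files named `<patient_id>_<kind>.nii.gz`.
#'
#' @param phantom Output of [build_phantom()].
#' @param dir Output directory (created if missing).
#' @param patient_id File name stem.
#' @return The four paths, invisibly.
#' @export
write_phantom_nifti <- function(phantom, dir, patient_id = "phantom") {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  sp <- phantom$volume$spacing_mm
  paths <- c(
    conventional = file.path(dir, paste0(patient_id, "_conventional.nii.gz")),
    low = file.path(dir, paste0(patient_id, "_low.nii.gz")),
    high = file.path(dir, paste0(patient_id, "_high.nii.gz")),
    labels = file.path(dir, paste0(patient_id, "_labels.nii.gz"))
  )
  write_hu_volume(phantom$volume$conventional, sp, paths["conventional"])
  write_hu_volume(phantom$volume$low, sp, paths["low"])
  write_hu_volume(phantom$volume$high, sp, paths["high"])
  write_hu_volume(phantom$truth$label_map + 0, sp, paths["labels"])
  invisible(paths)
}
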