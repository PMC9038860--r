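#' Specification of a synthetic dual-energy spine phantom
#'
#' A thoracolumbar spine stand-in: `n_vertebrae` cylindrical vertebral
#' bodies stacked along the inferior--superior (last array) axis, each with
#' a cortical shell of pure mineral and a marrow interior whose fat /
#' soft-tissue / mineral composition follows the diffuse infiltration level
#' (see [infiltration_to_fractions()]). Optional spherical osteolytic
#' lesions (mineral 0, soft-dominant) overwrite the composition. Two
#' reference rods beside the spine -- pure subcutaneous-like fat and pure
#' paravertebral-muscle-like soft tissue -- support in-body BMD
#' calibration. Attenuation at all three energies comes from the forward
#' mixture model plus additive Gaussian noise.
#'
#' @param grid_shape Integer triple, voxels.
#' @param spacing_mm Voxel spacing, mm.
#' @param n_vertebrae Number of vertebral bodies (>= 1).
#' @param body_radius_mm,body_height_mm,gap_mm Cylinder geometry, mm.
#' @param cortical_thickness_mm Cortical shell thickness, mm.
#' @param infiltration Diffuse marrow infiltration fraction in \[0, 1\].
#' @param base_soft_fraction Soft-tissue fraction of uninfiltrated marrow.
#' @param infiltration_gain Slope of the affine infiltration to
#'   soft-fraction map.
#' @param true_bmd_mg_ml Trabecular mineral density ground truth, mg/ml.
#' @param marrow_mineral_fraction Mineral volume fraction of marrow in
#'   reference-density units; defaults to
#'   `true_bmd_mg_ml / reference_mineral_density` of the basis.
#' @param lesions List of `list(center_mm = c(x,y,z), radius_mm = r)`.
#' @param noise_sd_hu Additive Gaussian noise sd, HU, independent across
#'   energies.
#' @param seed Integer seed; identical seeds give bit-identical phantoms.
#' @param basis A [material_basis()].
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid_shape = c(48, 48, 216),
                         spacing_mm = c(1, 1, 1.5),
                         n_vertebrae = 18,
                         body_radius_mm = 12,
                         body_height_mm = 14,
                         gap_mm = 4,
                         cortical_thickness_mm = 3,
                         infiltration = 0,
                         base_soft_fraction = 0.05,
                         infiltration_gain = 0.6,
                         true_bmd_mg_ml = 97,
                         marrow_mineral_fraction = NULL,
                         lesions = list(),
                         noise_sd_hu = 15,
                         seed = 1L,
                         basis = material_basis()) {
  spec <- list(grid_shape = as.integer(grid_shape), spacing_mm = check_spacing(spacing_mm),
               n_vertebrae = as.integer(n_vertebrae),
               body_radius_mm = body_radius_mm, body_height_mm = body_height_mm,
               gap_mm = gap_mm, cortical_thickness_mm = cortical_thickness_mm,
               infiltration = infiltration, base_soft_fraction = base_soft_fraction,
               infiltration_gain = infiltration_gain,
               true_bmd_mg_ml = true_bmd_mg_ml,
               marrow_mineral_fraction = marrow_mineral_fraction %||%
                 (true_bmd_mg_ml / basis$reference_mineral_density),
               lesions = lesions, noise_sd_hu = noise_sd_hu,
               seed = as.integer(seed), basis = basis)
  if (length(spec$grid_shape) != 3 || any(spec$grid_shape < 4)) {
    stopf("grid_shape must be three dimensions of at least 4 voxels")
  }
  if (spec$n_vertebrae < 1) stopf("n_vertebrae must be >= 1")
  for (nm in c("body_radius_mm", "body_height_mm", "gap_mm")) {
    if (spec[[nm]] <= 0) stopf("%s must be > 0", nm)
  }
  if (spec$cortical_thickness_mm < 0) stopf("cortical_thickness_mm must be >= 0")
  if (spec$infiltration < 0 || spec$infiltration > 1) stopf("infiltration must be in [0, 1]")
  if (spec$noise_sd_hu < 0) stopf("noise_sd_hu must be >= 0")
  if (spec$base_soft_fraction + spec$infiltration_gain > 1 + 1e-12) {
    stopf("base_soft_fraction + infiltration_gain must be <= 1 so the soft fraction stays a fraction")
  }
  # the marrow composition must be admissible across the whole infiltration range
  infiltration_to_fractions(0, spec)
  infiltration_to_fractions(1, spec)
  structure(spec, class = "phantom_spec")
}

#' Marrow composition at a diffuse infiltration level
#'
#' Plasma-cell infiltration displaces fatty marrow with soft tissue: the
#' soft fraction rises affinely with infiltration
#' (`soft = base_soft_fraction + infiltration_gain * i`) at fat's expense,
#' while the mineral fraction stays at the marrow trabecular level.
#'
#' @param i Infiltration fraction in \[0, 1\].
#' @param spec A [phantom_spec()] (or any list with `base_soft_fraction`,
#'   `infiltration_gain`, `marrow_mineral_fraction`).
#' @return A [compartment_fractions()] object.
#' @export
infiltration_to_fractions <- function(i, spec) {
  if (any(i < 0 | i > 1)) stopf("infiltration must be in [0, 1]")
  soft <- spec$base_soft_fraction + spec$infiltration_gain * i
  mineral <- spec$marrow_mineral_fraction
  fat <- 1 - soft - mineral
  if (any(c(soft, mineral, fat) < -1e-9) || any(c(soft, mineral, fat) > 1 + 1e-9)) {
    stopf(paste0("infiltration map leaves [0, 1]: at i = %.3f, (fat, soft, mineral) = ",
                 "(%.3f, %.3f, %.3f); adjust base_soft_fraction / infiltration_gain / ",
                 "marrow_mineral_fraction"), i[1], fat[1], soft[1], mineral[1])
  }
  compartment_fractions(fat, soft, mineral)
}

# voxel-center coordinates (mm) along one axis
axis_centers <- function(n, spacing) (seq_len(n) - 0.5) * spacing

#' Build a dual-energy spine phantom
#'
#' Renders the geometry of a [phantom_spec()] into compartment-fraction
#' maps, a ground-truth label map (0 background, 1..n vertebrae counted
#' caudal to cranial, -1 lesion), and noisy HU volumes at the three
#' energies via the forward mixture model.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` (a [spectral_volume()]) and
#'   `truth` (class `phantom_truth`: `label_map`, `fraction_map` (list of
#'   `fat`/`soft`/`mineral` arrays), `fat_ref_mask`, `muscle_ref_mask`,
#'   `true_infiltration`, `true_bmd`).
#' @export
build_phantom <- function(spec) {
  if (!inherits(spec, "phantom_spec")) stopf("`spec` must be a phantom_spec")
  dims <- spec$grid_shape
  sp <- spec$spacing_mm
  xs <- axis_centers(dims[1], sp[1])
  ys <- axis_centers(dims[2], sp[2])
  zs <- axis_centers(dims[3], sp[3])
  cx <- dims[1] * sp[1] / 2
  cy <- dims[2] * sp[2] / 2

  # in-plane radial distance from the spine axis, one slice worth
  r2 <- outer((xs - cx)^2, (ys - cy)^2, `+`)
  in_body2d <- r2 <= spec$body_radius_mm^2
  in_marrow2d <- r2 <= (spec$body_radius_mm - spec$cortical_thickness_mm)^2
  if (!any(in_body2d)) stopf("body_radius_mm too small for the grid spacing")

  pitch <- spec$body_height_mm + spec$gap_mm
  z_top_needed <- spec$gap_mm / 2 + spec$n_vertebrae * pitch - spec$gap_mm / 2
  label_map <- array(0L, dims)
  for (v in seq_len(spec$n_vertebrae)) {
    z0 <- spec$gap_mm / 2 + (v - 1) * pitch
    z1 <- z0 + spec$body_height_mm
    if (z1 > dims[3] * sp[3] + 1e-9) {
      stopf("vertebra %d (z %.1f-%.1f mm) exceeds the grid extent of %.1f mm",
            v, z0, z1, dims[3] * sp[3])
    }
    zi <- which(zs > z0 & zs < z1)
    if (length(zi) == 0) stopf("vertebra %d spans no voxel slice; refine spacing", v)
    label_map[, , zi][in_body2d] <- v
  }

  # marrow = interior both radially and axially (cortical end plates)
  marrow <- array(FALSE, dims)
  for (v in seq_len(spec$n_vertebrae)) {
    z0 <- spec$gap_mm / 2 + (v - 1) * pitch + spec$cortical_thickness_mm
    z1 <- z0 + spec$body_height_mm - 2 * spec$cortical_thickness_mm
    zi <- which(zs > z0 & zs < z1)
    marrow[, , zi][in_marrow2d] <- TRUE
  }

  # calibration reference rods flanking the spine, spanning the full stack
  rod_r <- 3
  rod_off <- spec$body_radius_mm + 6
  fat_rod2d <- outer((xs - (cx - rod_off))^2, (ys - cy)^2, `+`) <= rod_r^2
  mus_rod2d <- outer((xs - (cx + rod_off))^2, (ys - cy)^2, `+`) <= rod_r^2
  if (!any(fat_rod2d) || !any(mus_rod2d)) {
    stopf("grid too narrow for the calibration reference rods (need x extent >= %.0f mm)",
          2 * (rod_off + rod_r))
  }
  zspine <- zs < z_top_needed
  fat_ref <- array(fat_rod2d, dims) & rep(zspine, each = dims[1] * dims[2])
  mus_ref <- array(mus_rod2d, dims) & rep(zspine, each = dims[1] * dims[2])

  frac_fat <- array(0, dims); frac_soft <- array(0, dims); frac_min <- array(0, dims)
  body <- label_map > 0L
  cortex <- body & !marrow
  frac_min[cortex] <- 1
  mf <- infiltration_to_fractions(spec$infiltration, spec)
  frac_fat[marrow] <- mf[["fat"]]
  frac_soft[marrow] <- mf[["soft"]]
  frac_min[marrow] <- mf[["mineral"]]
  frac_fat[fat_ref] <- 1
  frac_soft[mus_ref] <- 1

  # osteolytic lesions: spheres of soft-dominant, mineral-free tissue
  for (les in spec$lesions) {
    ctr <- les$center_mm
    d2 <- outer(outer((xs - ctr[1])^2, (ys - ctr[2])^2, `+`), (zs - ctr[3])^2, `+`)
    inside <- d2 <= les$radius_mm^2 & body
    if (!any(inside)) next
    frac_fat[inside] <- 0.1
    frac_soft[inside] <- 0.9
    frac_min[inside] <- 0
    label_map[inside] <- -1L
  }

  defined <- body | label_map == -1L | fat_ref | mus_ref
  basis <- spec$basis
  hu_for <- function(energy) {
    hu <- array(-1000, dims)  # air background
    co <- switch(energy,
                 conventional = c(basis$hu_fat_conv, basis$hu_soft_conv, basis$hu_mineral_conv),
                 low = c(basis$hu_fat_low, basis$hu_soft_low, basis$hu_mineral_low),
                 high = c(basis$hu_fat_high, basis$hu_soft_high, basis$hu_mineral_high))
    hu[defined] <- frac_fat[defined] * co[1] + frac_soft[defined] * co[2] +
      frac_min[defined] * co[3]
    hu
  }
  conv <- hu_for("conventional"); low <- hu_for("low"); high <- hu_for("high")
  if (spec$noise_sd_hu > 0) {
    set.seed(spec$seed)
    nvox <- prod(dims)
    conv <- conv + array(stats::rnorm(nvox, 0, spec$noise_sd_hu), dims)
    low <- low + array(stats::rnorm(nvox, 0, spec$noise_sd_hu), dims)
    high <- high + array(stats::rnorm(nvox, 0, spec$noise_sd_hu), dims)
  }

  truth <- structure(list(
    label_map = label_map,
    fraction_map = list(fat = frac_fat, soft = frac_soft, mineral = frac_min),
    fat_ref_mask = fat_ref, muscle_ref_mask = mus_ref,
    true_infiltration = spec$infiltration,
    true_bmd = spec$marrow_mineral_fraction * basis$reference_mineral_density
  ), class = "phantom_truth")
  list(volume = spectral_volume(conv, low, high, sp), truth = truth)
}
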