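#' Three-compartment material basis
#'
#' Attenuation (HU) of the three pure compartments -- fat, soft tissue, and
#' bone mineral -- at the two acquisition energies and on the
#' conventional-equivalent image. A marrow voxel is modeled as a volume
#' mixture of the three; the mineral entry refers to hydroxyapatite-like
#' mineral at `reference_mineral_density` (so a voxel holding mineral at
#' twice the reference density contributes twice the mineral HU).
#'
#' Default values are synthetic conventions chosen so that calcium
#' attenuates more at the low energy (`hu_mineral_low > hu_mineral_high`),
#' fat is negative and mineral strongly positive, which is all the
#' two-basis suppression solve requires.
#'
#' @param hu_fat_conv,hu_fat_low,hu_fat_high HU of pure fat.
#' @param hu_soft_conv,hu_soft_low,hu_soft_high HU of pure soft tissue.
#' @param hu_mineral_conv,hu_mineral_low,hu_mineral_high HU of reference
#'   mineral at `reference_mineral_density`.
#' @param reference_mineral_density mg/ml of the mineral reference.
#' @return An object of class `material_basis`.
#' @export
material_basis <- function(hu_fat_conv = -100, hu_fat_low = -110, hu_fat_high = -90,
                           hu_soft_conv = 45, hu_soft_low = 50, hu_soft_high = 40,
                           hu_mineral_conv = 1000, hu_mineral_low = 1400,
                           hu_mineral_high = 800,
                           reference_mineral_density = 400) {
  b <- list(
    hu_fat_conv = hu_fat_conv, hu_fat_low = hu_fat_low, hu_fat_high = hu_fat_high,
    hu_soft_conv = hu_soft_conv, hu_soft_low = hu_soft_low, hu_soft_high = hu_soft_high,
    hu_mineral_conv = hu_mineral_conv, hu_mineral_low = hu_mineral_low,
    hu_mineral_high = hu_mineral_high,
    reference_mineral_density = reference_mineral_density
  )
  if (!all(vapply(b, function(x) is.numeric(x) && length(x) == 1 && is.finite(x), TRUE))) {
    stopf("all material basis entries must be finite scalars")
  }
  if (b$hu_mineral_low <= b$hu_mineral_high) {
    stopf("mineral must attenuate more at low energy (hu_mineral_low > hu_mineral_high)")
  }
  if (!(b$hu_fat_conv < 0 && b$hu_fat_low < 0 && b$hu_fat_high < 0)) {
    stopf("fat HU must be negative at every energy")
  }
  if (!(b$hu_mineral_conv > 0 && b$hu_mineral_low > 0 && b$hu_mineral_high > 0)) {
    stopf("mineral HU must be positive at every energy")
  }
  if (b$reference_mineral_density <= 0) stopf("reference_mineral_density must be > 0")
  structure(b, class = "material_basis")
}

#' Compartment volume fractions of a voxel
#'
#' @param fat,soft,mineral Volume fractions in \[0, 1\]; must sum to 1.
#' @return An object of class `compartment_fractions` (named numeric).
#' @export
compartment_fractions <- function(fat, soft, mineral) {
  f <- c(fat = fat, soft = soft, mineral = mineral)
  if (any(f < -1e-9) || any(f > 1 + 1e-9)) {
    stopf("compartment fractions must lie in [0, 1], got (%.4f, %.4f, %.4f)",
          fat, soft, mineral)
  }
  if (abs(sum(f) - 1) > 1e-9) {
    stopf("compartment fractions must sum to 1 (got %.12f)", sum(f))
  }
  structure(pmin(pmax(f, 0), 1), class = "compartment_fractions")
}

#' Forward mixture attenuation
#'
#' Volume-weighted linear combination of the pure-compartment HU values at
#' the requested energy: the total attenuation of a marrow voxel is the sum
#' of its fat, soft-tissue and mineral contributions.
#'
#' @param f A `compartment_fractions` object, a length-3 numeric
#'   (fat, soft, mineral), or an n x 3 matrix of fractions.
#' @param basis A [material_basis()].
#' @param energy One of `"conventional"`, `"low"`, `"high"`.
#' @return HU value(s).
#' @export
mixture_hu <- function(f, basis = material_basis(), energy = "conventional") {
  hu <- switch(energy,
    conventional = c(basis$hu_fat_conv, basis$hu_soft_conv, basis$hu_mineral_conv),
    low = c(basis$hu_fat_low, basis$hu_soft_low, basis$hu_mineral_low),
    high = c(basis$hu_fat_high, basis$hu_soft_high, basis$hu_mineral_high),
    stopf("unknown energy tag '%s' (use conventional/low/high)", energy)
  )
  if (is.matrix(f)) {
    if (ncol(f) != 3) stopf("fraction matrix must have 3 columns (fat, soft, mineral)")
    return(drop(f %*% hu))
  }
  if (length(f) != 3) stopf("`f` must hold 3 fractions (fat, soft, mineral)")
  sum(as.numeric(f) * hu)
}

#' A co-registered dual-energy HU volume set
#'
#' @param conventional,low,high 3-D HU arrays of identical shape.
#' @param spacing_mm Voxel spacing (mm), length 3.
#' @return An object of class `spectral_volume`.
#' @export
spectral_volume <- function(conventional, low, high, spacing_mm) {
  check_grid3d(conventional, "conventional")
  check_grid3d(low, "low")
  check_grid3d(high, "high")
  if (!identical(dim(conventional), dim(low)) || !identical(dim(conventional), dim(high))) {
    stopf("conventional/low/high grids must share one shape")
  }
  structure(list(conventional = conventional, low = low, high = high,
                 spacing_mm = check_spacing(spacing_mm)),
            class = "spectral_volume")
}

# closed-form 2x2 solve shared by vnca_transform and mineral_density_map:
# express (low, high) HU as fat background plus soft and mineral excesses,
#   HU_e = hu_fat_e + u * (hu_soft_e - hu_fat_e) + m * (hu_mineral_e - hu_fat_e)
# and invert for (u, m); m is mineral in reference-density units and may
# exceed 1 for denser-than-reference calcifications.
solve_soft_mineral <- function(low, high, basis) {
  bs_l <- basis$hu_soft_low - basis$hu_fat_low
  bs_h <- basis$hu_soft_high - basis$hu_fat_high
  bm_l <- basis$hu_mineral_low - basis$hu_fat_low
  bm_h <- basis$hu_mineral_high - basis$hu_fat_high
  det <- bs_l * bm_h - bm_l * bs_h
  scale <- max(abs(c(bs_l, bs_h, bm_l, bm_h)))^2
  if (abs(det) < 1e-8 * scale) {
    stopf("singular material basis: mineral response is parallel to the soft-fat direction")
  }
  r_l <- low - basis$hu_fat_low
  r_h <- high - basis$hu_fat_high
  list(
    soft = (bm_h * r_l - bm_l * r_h) / det,
    mineral = (bs_l * r_h - bs_h * r_l) / det
  )
}

#' Virtual non-calcium transform
#'
#' Per voxel, the paired low/high-energy HU values are decomposed into a
#' soft-tissue excess and a mineral content (in reference-density units) by
#' a closed-form 2x2 solve against the material basis. The calcium-
#' suppressed value is the conventional HU with a fraction `s` of the
#' estimated mineral contribution removed and the remaining non-mineral
#' sub-voxel renormalized to full volume:
#' `vnca = (conv - s * m * hu_mineral_conv) / (1 - s * m)`.
#'
#' The suppression strength is `s = suppression_index / 25`, clipped to
#' \[0, 1\], so an index of 25 means complete suppression. Voxels whose
#' estimated non-mineral volume vanishes (dense calcification, e.g.
#' cortical bone) have no marrow content to renormalize and are mapped to
#' the HU scale floor of -1024, which is what produces the characteristic
#' spike at the far-left end of VNCa marrow histograms. Output is clamped
#' to the CT scale \[-1024, 3071\].
#'
#' @param v A [spectral_volume()].
#' @param basis A [material_basis()].
#' @param suppression_index Suppression strength on the vendor-style scale
#'   where 25 is complete removal.
#' @return An object of class `vnca_volume` with fields `vnca`,
#'   `spacing_mm`, `suppression_index`.
#' @export
vnca_transform <- function(v, basis = material_basis(), suppression_index = 25) {
  if (!inherits(v, "spectral_volume")) stopf("`v` must be a spectral_volume")
  if (!is.numeric(suppression_index) || suppression_index <= 0) {
    stopf("suppression_index must be > 0")
  }
  s <- min(max(suppression_index / 25, 0), 1)
  sol <- solve_soft_mineral(v$low, v$high, basis)
  m_eff <- s * sol$mineral
  nonmin <- 1 - m_eff
  vnca <- v$conventional
  ok <- nonmin > 1e-3
  vnca[ok] <- (v$conventional[ok] - m_eff[ok] * basis$hu_mineral_conv) / nonmin[ok]
  vnca[!ok] <- -1024
  vnca <- pmin(pmax(vnca, -1024), 3071)
  dim(vnca) <- dim(v$conventional)
  structure(list(vnca = vnca, spacing_mm = v$spacing_mm,
                 suppression_index = suppression_index),
            class = "vnca_volume")
}

#' Per-voxel mineral density estimate
#'
#' Reuses the two-basis solve of [vnca_transform()] and scales the mineral
#' coefficient by the basis reference density.
#'
#' @inheritParams vnca_transform
#' @return 3-D array of mg/ml mineral density estimates.
#' @export
mineral_density_map <- function(v, basis = material_basis()) {
  if (!inherits(v, "spectral_volume")) stopf("`v` must be a spectral_volume")
  sol <- solve_soft_mineral(v$low, v$high, basis)
  d <- sol$mineral * basis$reference_mineral_density
  dim(d) <- dim(v$low)
  d
}
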