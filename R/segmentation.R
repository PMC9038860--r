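#' Rule-based vertebra labeling for spine phantoms
#'
#' Thresholds the conventional image at `bone_threshold`, fills each
#' cross-section's interior (so the marrow and any intraosseous lesion
#' cavity belong to the body), locates vertebral bodies as contiguous runs
#' of bone-bearing slices along the inferior--superior axis, splits merged
#' bodies at axial bone-profile minima, and labels them caudal to cranial.
#' An imported label map (e.g. from an external CNN) can be used instead
#' via [labeled_spine()].
#'
#' @param conventional 3-D conventional HU array.
#' @param spacing_mm Voxel spacing, mm.
#' @param bone_threshold HU threshold separating cortical bone (default
#'   +200 HU).
#' @param axis Inferior--superior array axis (default 3; the NIfTI reader
#'   reorients to RAS so axis 3 is superior).
#' @return A [labeled_spine()].
#' @export
label_vertebrae <- function(conventional, spacing_mm, bone_threshold = 200, axis = 3) {
  check_grid3d(conventional, "conventional")
  spacing_mm <- check_spacing(spacing_mm)
  if (axis != 3) stopf("only axis = 3 (last array axis) is supported")
  bone <- conventional > bone_threshold
  profile <- apply(bone, 3, sum)
  if (all(profile == 0)) stopf("no spine found: no voxels above %g HU", bone_threshold)

  # slices carrying a real cross-section (not a thin fusion bridge)
  min_count <- max(1, ceiling(0.05 * max(profile)))
  on <- profile >= min_count
  runs <- rle(on)
  ends <- cumsum(runs$lengths)
  starts <- ends - runs$lengths + 1
  seg <- list()
  for (k in seq_along(runs$values)) {
    if (!runs$values[k]) next
    idx <- starts[k]:ends[k]
    # split merged bodies at interior local minima of the bone profile
    if (length(idx) >= 5) {
      p <- profile[idx]
      L <- length(p)
      j <- 2:(L - 1)
      # a genuine fusion bridge carries far less bone than a body section
      is_cut <- p[j] < p[j - 1] & p[j] <= p[j + 1] & p[j] < 0.2 * max(p)
      cuts <- idx[j[is_cut]]
      if (length(cuts)) {
        grp <- cumsum(idx %in% cuts)
        for (piece in split(setdiff(idx, cuts), grp[!(idx %in% cuts)])) {
          if (length(piece)) seg[[length(seg) + 1]] <- piece
        }
        next
      }
    }
    seg[[length(seg) + 1]] <- idx
  }
  seg <- seg[order(vapply(seg, min, 1L))]

  label_map <- array(0L, dim(conventional))
  for (v in seq_along(seg)) {
    zi <- seg[[v]]
    filled <- fill_sections(bone[, , zi, drop = FALSE])
    label_map[, , zi][filled] <- v
  }
  labeled_spine(label_map, spacing_mm)
}

# per-slice interior fill: a voxel is inside a cross-section if it sees
# bone on both sides along x and along y (exact for convex bodies)
fill_sections <- function(bone) {
  d <- dim(bone)
  dir_cum <- function(b, dim, rev) {
    out <- b
    n <- d[dim]
    idx <- if (rev) (n - 1):1 else 2:n
    step <- if (rev) 1L else -1L
    for (i in idx) {
      if (dim == 1) out[i, , ] <- out[i, , ] | out[i + step, , ]
      else out[, i, ] <- out[, i, ] | out[, i + step, ]
    }
    out
  }
  if (d[1] < 2 || d[2] < 2) return(bone)
  dir_cum(bone, 1, FALSE) & dir_cum(bone, 1, TRUE) &
    dir_cum(bone, 2, FALSE) & dir_cum(bone, 2, TRUE)
}

#' Labeled spine container
#'
#' Wraps an integer vertebra label map (positive labels; 0 background; -1
#' allowed for lesion voxels, which never join the ordering) together with
#' the caudal-to-cranial ordering of its labels by centroid along the
#' inferior--superior axis.
#'
#' @param label_map Integer 3-D array.
#' @param spacing_mm Voxel spacing, mm.
#' @return An object of class `labeled_spine`.
#' @export
labeled_spine <- function(label_map, spacing_mm) {
  check_grid3d(label_map, "label_map")
  spacing_mm <- check_spacing(spacing_mm)
  labs <- sort(unique(label_map[label_map > 0]))
  if (length(labs) == 0) stopf("no spine found: label map holds no positive labels")
  zc <- slice_counts_by_label(label_map, labs)
  centroid_z <- vapply(seq_along(labs), function(i) {
    w <- zc[i, ]
    sum(w * seq_along(w)) / sum(w)
  }, 1)
  ordering <- labs[order(centroid_z)]
  structure(list(label_map = label_map, spacing_mm = spacing_mm, ordering = ordering),
            class = "labeled_spine")
}

# label x slice count matrix (how many voxels of each label per z slice)
slice_counts_by_label <- function(label_map, labs) {
  nz <- dim(label_map)[3]
  out <- matrix(0, length(labs), nz)
  for (z in seq_len(nz)) {
    sl <- label_map[, , z]
    sl <- sl[sl > 0]
    if (length(sl)) {
      tb <- tabulate(match(sl, labs), nbins = length(labs))
      out[, z] <- tb
    }
  }
  out
}

#' Select the k most caudal vertebrae as a VOI
#'
#' The marrow volume of interest is limited to `k` vertebrae counting from
#' the bottom upwards (default 17, the thoracolumbar stack).
#'
#' @param ls A [labeled_spine()].
#' @param k Number of caudal vertebrae to keep.
#' @return A [voi_mask()] covering the union of the selected labels.
#' @export
select_bottom_k <- function(ls, k = 17) {
  if (!inherits(ls, "labeled_spine")) stopf("`ls` must be a labeled_spine")
  n <- length(ls$ordering)
  if (n < k) stopf("found %d < %d vertebrae", n, k)
  keep <- ls$ordering[seq_len(k)]
  voi_mask(array(ls$label_map %in% keep, dim(ls$label_map)), ls$spacing_mm)
}

#' Boolean volume-of-interest mask
#'
#' @param mask Logical 3-D array.
#' @param spacing_mm Voxel spacing, mm.
#' @return An object of class `voi_mask` with derived `volume_cm3`.
#' @export
voi_mask <- function(mask, spacing_mm) {
  check_grid3d(mask, "mask")
  if (!is.logical(mask)) stopf("`mask` must be logical")
  spacing_mm <- check_spacing(spacing_mm)
  structure(list(mask = mask, spacing_mm = spacing_mm,
                 volume_cm3 = sum(mask) * prod(spacing_mm) / 1000),
            class = "voi_mask")
}

# integer offsets of a discrete ball of physical radius r on an
# anisotropic lattice (voxel kept by erosion iff the ball fits inside)
ball_offsets <- function(radius_mm, spacing_mm) {
  nmax <- floor(radius_mm / spacing_mm + 1e-9)
  g <- expand.grid(dx = -nmax[1]:nmax[1], dy = -nmax[2]:nmax[2], dz = -nmax[3]:nmax[3])
  d2 <- (g$dx * spacing_mm[1])^2 + (g$dy * spacing_mm[2])^2 + (g$dz * spacing_mm[3])^2
  g[d2 <= radius_mm^2 + 1e-9, , drop = FALSE]
}

#' Morphological erosion by a physical-radius ball
#'
#' Erodes the mask by a discrete ball of radius `radius_mm` honoring the
#' anisotropic voxel spacing: a voxel survives iff every voxel whose center
#' lies within `radius_mm` of it belongs to the mask (volume outside the
#' grid counts as background). Used with the default 3 mm to strip the
#' bordering cortical bone, which holds no marrow, from the vertebral VOI.
#'
#' @param m A [voi_mask()].
#' @param radius_mm Erosion radius, mm (>= 0; 0 is the identity).
#' @return An eroded [voi_mask()]; warns and returns an empty mask if the
#'   radius swallows the whole VOI.
#' @export
erode_cortex <- function(m, radius_mm = 3) {
  if (!inherits(m, "voi_mask")) stopf("`m` must be a voi_mask")
  if (radius_mm < 0) stopf("radius_mm must be >= 0")
  if (radius_mm == 0 || !any(m$mask)) return(m)
  off <- ball_offsets(radius_mm, m$spacing_mm)
  eroded <- erode_mask_offsets(m$mask, off)
  if (!any(eroded)) {
    warnf("erosion by %.1f mm removed the entire VOI", radius_mm)
  }
  voi_mask(eroded, m$spacing_mm)
}

erode_mask_offsets <- function(mask, off) {
  d <- dim(mask)
  # crop to the bounding box (padded) to keep the shifts cheap
  w <- which(mask, arr.ind = TRUE)
  pad <- c(max(abs(off$dx)), max(abs(off$dy)), max(abs(off$dz)))
  lo <- pmax(apply(w, 2, min) - pad, 1)
  hi <- pmin(apply(w, 2, max) + pad, d)
  sub <- mask[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
  ds <- dim(sub)
  out <- sub
  for (k in seq_len(nrow(off))) {
    dx <- off$dx[k]; dy <- off$dy[k]; dz <- off$dz[k]
    if (dx == 0 && dy == 0 && dz == 0) next
    shifted <- array(FALSE, ds)
    sx <- seq_len(ds[1]) + dx; sy <- seq_len(ds[2]) + dy; sz <- seq_len(ds[3]) + dz
    vx <- sx >= 1 & sx <= ds[1]; vy <- sy >= 1 & sy <= ds[2]; vz <- sz >= 1 & sz <= ds[3]
    shifted[vx, vy, vz] <- sub[sx[vx], sy[vy], sz[vz], drop = FALSE]
    out <- out & shifted
    if (!any(out)) break
  }
  res <- array(FALSE, d)
  res[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- out
  # voxels whose ball leaves the grid entirely: handled by construction,
  # since out-of-grid neighbours were never marked TRUE in `shifted`
  res
}

#' Extract the marrow attenuation sample
#'
#' Applies a VOI mask to a VNCa volume and returns the multiset of HU
#' values inside the mask together with the mask volume.
#'
#' @param v A `vnca_volume` (from [vnca_transform()]) or a bare 3-D array.
#' @param m A [voi_mask()].
#' @return An object of class `marrow_sample`: list with `hu` (numeric
#'   vector) and `voi_volume_cm3`.
#' @export
extract_voxels <- function(v, m) {
  arr <- if (inherits(v, "vnca_volume")) v$vnca else v
  check_grid3d(arr, "v")
  if (!inherits(m, "voi_mask")) stopf("`m` must be a voi_mask")
  if (!identical(dim(arr), dim(m$mask))) {
    stopf("shape mismatch: volume %s vs mask %s",
          paste(dim(arr), collapse = "x"), paste(dim(m$mask), collapse = "x"))
  }
  structure(list(hu = as.numeric(arr[m$mask]), voi_volume_cm3 = m$volume_cm3),
            class = "marrow_sample")
}
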