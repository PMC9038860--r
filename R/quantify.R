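#' Attenuation histogram specification
#'
#' The marrow histogram convention: bins of width 5 HU over
#' \[-1024, +3071\] HU, left-closed right-open, and a standardization
#' volume of 336.0 cm3 so histograms of differently sized VOIs cover the
#' same area.
#'
#' @param lower_edge,upper_edge HU range.
#' @param bin_width HU per bin; the range must divide evenly.
#' @param standard_volume_cm3 Common VOI volume histograms are scaled to.
#' @return An object of class `histogram_spec`.
#' @export
histogram_spec <- function(lower_edge = -1024, upper_edge = 3071, bin_width = 5,
                           standard_volume_cm3 = 336.0) {
  if (upper_edge <= lower_edge) stopf("upper_edge must exceed lower_edge")
  if (bin_width <= 0) stopf("bin_width must be > 0")
  nb <- (upper_edge - lower_edge) / bin_width
  if (abs(nb - round(nb)) > 1e-9) {
    stopf("(upper_edge - lower_edge) must be divisible by bin_width")
  }
  if (standard_volume_cm3 <= 0) stopf("standard_volume_cm3 must be > 0")
  structure(list(lower_edge = lower_edge, upper_edge = upper_edge,
                 bin_width = bin_width, standard_volume_cm3 = standard_volume_cm3),
            class = "histogram_spec")
}

#' Bin a marrow attenuation sample
#'
#' Counts voxels into left-closed right-open bins `[e, e + width)`.
#' Values outside the range are excluded from the bins but reported in the
#' `n_out_of_range` attribute, so counts + out-of-range tally always equal
#' the sample size.
#'
#' @param sample A `marrow_sample` from [extract_voxels()] or a numeric
#'   vector of HU values.
#' @param spec A [histogram_spec()].
#' @return A tibble of class `attenuation_histogram` with columns
#'   `bin_lower`, `bin_upper`, `count` and attributes `voi_volume_cm3`,
#'   `n_out_of_range`, `spec`.
#' @export
attenuation_histogram <- function(sample, spec = histogram_spec()) {
  hu <- if (inherits(sample, "marrow_sample")) sample$hu else as.numeric(sample)
  vol <- if (inherits(sample, "marrow_sample")) sample$voi_volume_cm3 else NA_real_
  if (any(!is.finite(hu))) stopf("sample must be finite")
  edges <- seq(spec$lower_edge, spec$upper_edge, by = spec$bin_width)
  nb <- length(edges) - 1
  in_range <- hu >= spec$lower_edge & hu < spec$upper_edge
  bin <- floor((hu[in_range] - spec$lower_edge) / spec$bin_width) + 1
  counts <- tabulate(bin, nbins = nb)
  out <- tibble::tibble(bin_lower = edges[-length(edges)], bin_upper = edges[-1],
                        count = counts)
  attr(out, "voi_volume_cm3") <- vol
  attr(out, "n_out_of_range") <- sum(!in_range)
  attr(out, "spec") <- spec
  class(out) <- c("attenuation_histogram", class(out))
  out
}

#' Standardize a histogram to the common VOI volume
#'
#' Scales the counts by `standard_volume_cm3 / voi_volume_cm3`, so any two
#' standardized histograms cover the same area and can be overlaid.
#'
#' @param h An [attenuation_histogram()] with a known VOI volume.
#' @param spec A [histogram_spec()].
#' @return `h` with an added `standardized_count` column.
#' @export
standardize_histogram <- function(h, spec = attr(h, "spec") %||% histogram_spec()) {
  vol <- attr(h, "voi_volume_cm3")
  if (is.null(vol) || is.na(vol) || vol <= 0) {
    stopf("histogram has no positive VOI volume to standardize")
  }
  h$standardized_count <- h$count * spec$standard_volume_cm3 / vol
  h
}

#' Non-fatty portion of bone marrow
#'
#' The headline statistic: the percentage of marrow VOI voxels with VNCa
#' attenuation strictly above 0 HU among voxels strictly above -1000 HU
#' (the sub--1000 HU tail produced by virtual calcium removal of dense
#' calcification is not marrow and is excluded from the denominator).
#' Computed from the raw voxel sample, not from binned counts, to avoid
#' 5-HU quantization bias.
#'
#' @param sample A `marrow_sample` or numeric vector of VNCa HU values.
#' @return A one-row tibble of class `marrow_statistic`: `non_fatty_percent`,
#'   `n_above_zero`, `n_marrow`, `voi_volume_cm3`.
#' @export
non_fatty_portion <- function(sample) {
  hu <- if (inherits(sample, "marrow_sample")) sample$hu else as.numeric(sample)
  vol <- if (inherits(sample, "marrow_sample")) sample$voi_volume_cm3 else NA_real_
  if (any(!is.finite(hu))) stopf("sample must be finite")
  n_marrow <- sum(hu > -1000)
  if (n_marrow == 0) stopf("no marrow voxels (none above -1000 HU)")
  n_above <- sum(hu > 0)
  out <- tibble::tibble(non_fatty_percent = 100 * n_above / n_marrow,
                        n_above_zero = n_above, n_marrow = n_marrow,
                        voi_volume_cm3 = vol)
  class(out) <- c("marrow_statistic", class(out))
  out
}
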