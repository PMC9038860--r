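#' Plot a marrow attenuation histogram
#'
#' Step plot of (standardized, if available) voxel counts over the marrow
#' HU range; the view defaults to the informative -400..400 HU window but
#' the full range can be requested.
#'
#' @param object An [attenuation_histogram()].
#' @param xlim HU window to display.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.attenuation_histogram <- function(object, xlim = c(-400, 400), ...) {
  ycol <- if ("standardized_count" %in% names(object)) "standardized_count" else "count"
  df <- as.data.frame(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_lower, y = .data[[ycol]])) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "VNCa attenuation (HU)",
                  y = if (ycol == "standardized_count") "standardized voxel count" else
                    "voxel count",
                  title = "Bone marrow attenuation histogram") +
    ggplot2::theme_minimal()
}

#' Overlay group-mean marrow histograms of a pipeline report
#'
#' The classic two-group overlay: mean standardized VNCa histograms for
#' the myeloma and MGUS groups cover the same area, with the MGUS peak
#' typically higher and shifted toward more negative attenuation.
#'
#' @param report A `vnca_report` (or its `histograms` tibble).
#' @param xlim HU window to display.
#' @return A ggplot.
#' @export
plot_group_histograms <- function(report, xlim = c(-400, 400)) {
  h <- if (inherits(report, "vnca_report")) report$histograms else report
  ggplot2::ggplot(as.data.frame(h),
                  ggplot2::aes(x = .data$bin_lower, y = .data$standardized_count,
                               colour = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::coord_cartesian(xlim = xlim) +
    ggplot2::labs(x = "VNCa attenuation (HU)", y = "standardized voxel count",
                  colour = NULL,
                  title = "Marrow attenuation by group (standardized to 336 cm³)") +
    ggplot2::theme_minimal()
}

#' Plot the infiltration regression
#'
#' Scatter of the logit-compressed biopsy infiltration against the
#' non-fatty portion of bone marrow, with the model line at the cohort
#' mean BMD and a 95% confidence band.
#'
#' @param object A `marrow_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.marrow_fit <- function(object, ...) {
  d <- object$data
  grid <- data.frame(
    non_fatty_percent = seq(min(d$non_fatty_percent), max(d$non_fatty_percent),
                            length.out = 80),
    bmd_mg_ml = mean(d$bmd_mg_ml))
  pr <- stats::predict(object$fit, grid, interval = "confidence")
  grid <- cbind(grid, as.data.frame(pr))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$non_fatty_percent, y = .data$y)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(y = .data$fit, ymin = .data$lwr, ymax = .data$upr),
                         alpha = 0.2) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "non-fatty portion of bone marrow (%)",
                  y = "logit biopsy infiltration",
                  title = "Infiltration vs non-fatty marrow portion") +
    ggplot2::theme_minimal()
}

#' Plot an ROC curve
#'
#' @param object A `roc_result`.
#' @param ... Unused.
#' @return A ggplot with the Youden operating point marked.
#' @export
autoplot.roc_result <- function(object, ...) {
  cv <- as.data.frame(object$curve[order(object$curve$threshold, decreasing = TRUE), ])
  op <- data.frame(fpr = 1 - object$specificity, tpr = object$sensitivity)
  ggplot2::ggplot(cv, ggplot2::aes(x = 1 - .data$specificity, y = .data$sensitivity)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(data = op, ggplot2::aes(x = .data$fpr, y = .data$tpr), size = 2) +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC (AUC %.2f [%.2f-%.2f])",
                                  object$auc, object$ci_lower, object$ci_upper)) +
    ggplot2::theme_minimal()
}
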