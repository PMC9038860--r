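#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the infiltration regression
#'
#' One row per model term with the HC0 robust standard errors.
#'
#' @param x A `marrow_fit`.
#' @param ... Unused.
#' @return A tibble with `term`, `estimate`, `robust_se`, `statistic`,
#'   `p_value`.
#' @export
tidy.marrow_fit <- function(x, ...) x$coefficients

#' One-row model summary of the infiltration regression
#'
#' @param x A `marrow_fit`.
#' @param ... Unused.
#' @return A one-row tibble: `n`, `r_squared`, `model_r`, `partial_r`,
#'   `semipartial_r`, `bp_stat`, `bp_p`, `max_vif`.
#' @export
glance.marrow_fit <- function(x, ...) {
  tibble::tibble(n = x$n, r_squared = summary(x$fit)$r.squared,
                 model_r = x$model_r, partial_r = x$partial_r,
                 semipartial_r = x$semipartial_r,
                 bp_stat = x$bp_stat, bp_p = x$bp_p, max_vif = max(x$vif))
}

#' Tidy an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return The operating-point tibble (`threshold`, `sensitivity`,
#'   `specificity`).
#' @export
tidy.roc_result <- function(x, ...) x$curve

#' One-row summary of an ROC result
#'
#' @param x A `roc_result`.
#' @param ... Unused.
#' @return A one-row tibble with AUC, DeLong CI, Youden operating point
#'   and post-hoc power.
#' @export
glance.roc_result <- function(x, ...) {
  tibble::tibble(auc = x$auc, ci_lower = x$ci_lower, ci_upper = x$ci_upper,
                 youden_threshold = x$youden_threshold,
                 sensitivity = x$sensitivity, specificity = x$specificity,
                 n_cases = x$n_cases, n_controls = x$n_controls,
                 power_at_alpha = x$power_at_alpha)
}
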