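#' ROC analysis with Youden operating point
#'
#' Empirical (Mann--Whitney) AUC with a DeLong 95% confidence interval,
#' and the operating threshold maximizing Youden's J
#' (sensitivity + specificity - 1). Candidate thresholds are placed at the
#' midpoints between adjacent observed scores (plus sentinels outside the
#' range); a positive call is a score strictly above the threshold. Ties
#' in J are broken toward higher specificity, then toward the higher
#' threshold.
#'
#' @param scores Numeric predictor (higher = more disease-like).
#' @param labels Binary outcome (1 = case / positive class).
#' @param alpha Significance level for the post-hoc ROC power.
#' @return An object of class `roc_result`: list with `auc`, `ci_lower`,
#'   `ci_upper`, `youden_threshold`, `sensitivity`, `specificity`,
#'   `n_cases`, `n_controls`, `power_at_alpha`, and `curve` (a tibble of
#'   all candidate operating points).
#' @export
roc_youden <- function(scores, labels, alpha = 0.05) {
  scores <- as.numeric(scores)
  labels <- as.integer(labels)
  if (length(scores) != length(labels)) stopf("scores and labels disagree in length")
  if (any(is.na(scores)) || any(is.na(labels))) stopf("missing values not allowed")
  if (!all(labels %in% c(0L, 1L))) stopf("labels must be binary 0/1")
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  if (length(pos) == 0 || length(neg) == 0) stopf("both classes must be present")

  # Mann-Whitney AUC (ties count 1/2)
  r <- rank(scores)
  auc <- (sum(r[labels == 1]) - length(pos) * (length(pos) + 1) / 2) /
    (length(pos) * length(neg))

  ci <- tryCatch(suppressWarnings({
    ro <- pROC::roc(response = labels, predictor = scores, direction = "<",
                    levels = c(0, 1), quiet = TRUE)
    as.numeric(pROC::ci.auc(ro, method = "delong"))[c(1, 3)]
  }), error = function(e) c(NA_real_, NA_real_))

  u <- sort(unique(scores))
  thr <- if (length(u) == 1) c(u - 1, u + 1) else
    c(u[1] - 1, (u[-length(u)] + u[-1]) / 2, u[length(u)] + 1)
  sens <- vapply(thr, function(th) mean(pos > th), 1.0)
  spec <- vapply(thr, function(th) mean(neg <= th), 1.0)
  j <- sens + spec - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-spec[best], -thr[best])][1]

  power <- if (auc >= 1) 1 else if (auc <= 0.5) alpha else
    roc_power(auc, length(pos), length(neg), alpha)

  structure(list(auc = auc, ci_lower = ci[1], ci_upper = ci[2],
                 youden_threshold = thr[best],
                 sensitivity = sens[best], specificity = spec[best],
                 n_cases = length(pos), n_controls = length(neg),
                 power_at_alpha = power, alpha = alpha,
                 curve = tibble::tibble(threshold = thr, sensitivity = sens,
                                        specificity = spec)),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("AUC %.2f [%.2f-%.2f]; Youden threshold %.3g (sens %.2f, spec %.2f); power %.2f\n",
              x$auc, x$ci_lower, x$ci_upper, x$youden_threshold,
              x$sensitivity, x$specificity, x$power_at_alpha))
  invisible(x)
}

#' Confusion-matrix metrics
#'
#' Sensitivity, specificity and companions from the four counts, with the
#' printed two-decimal convention (half away from zero, so 5/8 prints as
#' 0.63) alongside the exact fractions.
#'
#' @param tp,fn,tn,fp Non-negative counts.
#' @return A one-row tibble: exact `sensitivity`, `specificity`, `ppv`,
#'   `npv`, `accuracy`, the two-decimal `sensitivity_2dp` /
#'   `specificity_2dp`, and the fraction strings.
#' @export
confusion_metrics <- function(tp, fn, tn, fp) {
  cnt <- c(tp = tp, fn = fn, tn = tn, fp = fp)
  if (any(cnt < 0) || any(cnt != round(cnt))) stopf("counts must be non-negative integers")
  if (tp + fn == 0) stopf("no positives (tp + fn = 0)")
  if (tn + fp == 0) stopf("no negatives (tn + fp = 0)")
  sens <- tp / (tp + fn)
  spec <- tn / (tn + fp)
  tibble::tibble(
    sensitivity = sens, specificity = spec,
    ppv = if (tp + fp > 0) tp / (tp + fp) else NA_real_,
    npv = if (tn + fn > 0) tn / (tn + fn) else NA_real_,
    accuracy = (tp + tn) / sum(cnt),
    sensitivity_2dp = round_half_up(sens, 2),
    specificity_2dp = round_half_up(spec, 2),
    sensitivity_frac = sprintf("%d/%d", tp, tp + fn),
    specificity_frac = sprintf("%d/%d", tn, tn + fp)
  )
}

#' Post-hoc power of the ROC AUC test
#'
#' Power of the two-sided test that the AUC differs from 0.5, under the
#' binormal model with Obuchowski's variance function for continuous
#' ratings,
#' `V(a) = 0.0099 e^(-a^2/2) ((5 a^2 + 8) + (a^2 + 8) / R) / n_cases`
#' with `a = qnorm(AUC) * sqrt(2)` and `R = n_controls / n_cases`; the
#' null variance is evaluated at AUC 0.5 and the alternative variance at
#' the stated AUC.
#'
#' @param auc Area under the curve, in \[0.5, 1).
#' @param n_cases,n_controls Group sizes (>= 2).
#' @param alpha Two-sided significance level.
#' @return Power in \[0, 1\].
#' @export
roc_power <- function(auc, n_cases, n_controls, alpha = 0.05) {
  if (auc < 0.5 || auc >= 1) stopf("auc must lie in [0.5, 1)")
  if (n_cases < 2 || n_controls < 2) stopf("both groups need >= 2 observations")
  if (alpha <= 0 || alpha >= 1) stopf("alpha must lie in (0, 1)")
  R <- n_controls / n_cases
  vfun <- function(a) 0.0099 * exp(-a^2 / 2) * ((5 * a^2 + 8) + (a^2 + 8) / R) / n_cases
  a1 <- stats::qnorm(auc) * sqrt(2)
  sd0 <- sqrt(vfun(0))
  sd1 <- sqrt(vfun(a1))
  z <- stats::qnorm(1 - alpha / 2)
  delta <- auc - 0.5
  stats::pnorm((delta - z * sd0) / sd1) + stats::pnorm((-delta - z * sd0) / sd1)
}

#' Apply a fixed decision cutoff to a cohort
#'
#' Classifies patients by `non_fatty_percent > cutoff` (the study-style
#' decision rule) and summarizes agreement with a binary outcome.
#'
#' @param scores Numeric predictor values.
#' @param labels Binary outcome.
#' @param cutoff Threshold on the predictor (default 0.93, percent).
#' @return [confusion_metrics()] row for the rule.
#' @export
apply_decision_rule <- function(scores, labels, cutoff = 0.93) {
  if (cutoff < 0) stopf("cutoff must be >= 0")
  pred <- as.integer(scores > cutoff)
  confusion_metrics(tp = sum(pred == 1 & labels == 1),
                    fn = sum(pred == 0 & labels == 1),
                    tn = sum(pred == 0 & labels == 0),
                    fp = sum(pred == 1 & labels == 0))
}
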