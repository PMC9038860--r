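#' Boundary-safe logit transform for bounded fractions
#'
#' Biopsy infiltration lives on \[0, 1\] and reaches both boundaries; the
#' usual remedy before a logit is the Smithson--Verkuilen compression
#' `(y * (n - 1) + 0.5) / n`, applied uniformly to all observations, then
#' the log-odds.
#'
#' @param y Fraction(s) in \[0, 1\].
#' @param n Sample size used for the compression (>= 2).
#' @return Transformed value(s).
#' @export
logit_bounded <- function(y, n) {
  if (n < 2) stopf("n must be >= 2")
  if (any(y < 0 | y > 1)) stopf("y must lie in [0, 1]")
  stats::qlogis((y * (n - 1) + 0.5) / n)
}

#' Breusch--Pagan heteroskedasticity test
#'
#' The studentized (Koenker) form: the LM statistic is `n * R^2` of the
#' auxiliary regression of squared residuals on the model design, referred
#' to a chi-squared distribution with as many degrees of freedom as
#' non-intercept design columns.
#'
#' @param design Numeric matrix or data frame of regressors (an intercept
#'   column is added if absent).
#' @param residuals Residuals of the fitted mean model.
#' @return A list with `statistic`, `p_value`, `df`.
#' @export
breusch_pagan <- function(design, residuals) {
  X <- as.matrix(design)
  if (!any(apply(X, 2, function(c) all(c == c[1])))) X <- cbind(`(Intercept)` = 1, X)
  n <- length(residuals)
  if (nrow(X) != n) stopf("design and residuals disagree in length")
  u2 <- residuals^2
  if (stats::var(u2) == 0) {
    return(list(statistic = 0, p_value = 1, df = ncol(X) - 1))
  }
  aux <- stats::lm.fit(X, u2)
  r2 <- 1 - sum(aux$residuals^2) / sum((u2 - mean(u2))^2)
  stat <- n * r2
  df <- ncol(X) - 1
  list(statistic = stat, p_value = stats::pchisq(stat, df, lower.tail = FALSE), df = df)
}

#' Infiltration regression with White robust errors
#'
#' Least squares of the logit-compressed biopsy infiltration on the
#' non-fatty portion of bone marrow with BMD as a control covariate.
#' Inference uses a White-type sandwich covariance with a t reference on
#' the residual degrees of freedom. The reported robust errors use the
#' leverage-adjusted HC3 weights, the standard recommendation for samples
#' of this size (White's original HC0 estimator over-rejects noticeably
#' below n of a few hundred); the plain HC0 matrix is also returned as
#' `vcov_hc0`, and the classical (homoskedastic) standard errors and
#' p-values are kept alongside. Heteroskedasticity is checked with the
#' Breusch--Pagan test, collinearity with variance inflation factors.
#' Because the flavour of the reported effect-size correlation is
#' ambiguous in this setting, the partial, semipartial and whole-model
#' correlations are all returned (`partial_r` is the headline one: the
#' correlation of predictor and transformed response given BMD).
#'
#' @param t Cohort tibble/data frame with columns `infiltration` (fraction
#'   in \[0, 1\]), `non_fatty_percent`, `bmd_mg_ml`.
#' @param min_n Minimum number of complete cases (default 10).
#' @return An object of class `marrow_fit`; see [tidy.marrow_fit()] and
#'   [glance.marrow_fit()].
#' @export
fit_infiltration_model <- function(t, min_n = 10) {
  need <- c("infiltration", "non_fatty_percent", "bmd_mg_ml")
  if (!all(need %in% names(t))) {
    stopf("cohort table must have columns %s", paste(need, collapse = ", "))
  }
  d <- t[stats::complete.cases(t[, need]), need, drop = FALSE]
  n <- nrow(d)
  if (n < min_n) stopf("need at least %d complete cases, got %d", min_n, n)
  d$y <- logit_bounded(d$infiltration, n)
  X <- stats::model.matrix(~ non_fatty_percent + bmd_mg_ml, d)
  if (qr(X)$rank < ncol(X)) stopf("rank-deficient design: predictors are collinear")
  fit <- stats::lm(y ~ non_fatty_percent + bmd_mg_ml, data = d)

  vc0 <- sandwich::vcovHC(fit, type = "HC0")
  vc3 <- sandwich::vcovHC(fit, type = "HC3")
  est <- stats::coef(fit)
  se <- sqrt(diag(vc3))
  tt <- est / se
  df <- fit$df.residual
  p <- 2 * stats::pt(-abs(tt), df)
  cls <- summary(fit)$coefficients
  coefs <- tibble::tibble(term = names(est), estimate = unname(est),
                          robust_se = unname(se), statistic = unname(tt),
                          p_value = unname(p),
                          classical_se = unname(cls[, 2]),
                          p_value_classical = unname(cls[, 4]))

  bp <- breusch_pagan(X[, -1, drop = FALSE], stats::residuals(fit))
  vifs <- car::vif(fit)

  # correlation flavours of the main predictor's effect
  r_y_given_b <- stats::residuals(stats::lm(y ~ bmd_mg_ml, data = d))
  r_x_given_b <- stats::residuals(stats::lm(non_fatty_percent ~ bmd_mg_ml, data = d))
  partial_r <- stats::cor(r_y_given_b, r_x_given_b)
  semipartial_r <- stats::cor(d$y, r_x_given_b)
  model_r <- sqrt(summary(fit)$r.squared)

  structure(list(fit = fit, coefficients = coefs, vcov_hc0 = vc0, vcov_hc3 = vc3,
                 vif = vifs, bp_stat = bp$statistic, bp_p = bp$p_value,
                 partial_r = partial_r, semipartial_r = semipartial_r,
                 model_r = model_r, n = n, data = d),
            class = "marrow_fit")
}

#' @export
print.marrow_fit <- function(x, ...) {
  cat(sprintf("Infiltration model (n = %d), White-type (HC3) robust inference\n", x$n))
  print(as.data.frame(x$coefficients), digits = 3)
  cat(sprintf("partial r (non-fatty | BMD) = %.2f; Breusch-Pagan p = %.3g; max VIF = %.2f\n",
              x$partial_r, x$bp_p, max(x$vif)))
  invisible(x)
}

#' Power of the F test for the main predictor at a given n
#'
#' Noncentral-F power of the 1-df test of one predictor in a linear model
#' with `n_predictors` regressors, at Cohen's effect size `f2`
#' (noncentrality `f2 * n`, denominator df `n - n_predictors - 1`).
#'
#' @param n Sample size.
#' @param f2 Cohen's f-squared.
#' @param alpha Significance level.
#' @param n_predictors Total predictors in the model.
#' @return Power in \[0, 1\].
#' @export
regression_power <- function(n, f2, alpha = 0.05, n_predictors = 2) {
  df2 <- n - n_predictors - 1
  if (df2 < 1) return(0)
  crit <- stats::qf(1 - alpha, 1, df2)
  1 - stats::pf(crit, 1, df2, ncp = f2 * n)
}

#' Required sample size for the infiltration regression
#'
#' Smallest n whose noncentral-F power for the main predictor reaches the
#' target (the G*Power-style a-priori calculation).
#'
#' @param f2 Cohen's f-squared effect size (study planning value 0.32).
#' @param alpha Significance level.
#' @param power Target power.
#' @param n_predictors Total predictors in the model.
#' @param n_max Search ceiling.
#' @return A list with `n` and `achieved_power`.
#' @export
regression_sample_size <- function(f2 = 0.32, alpha = 0.05, power = 0.8,
                                   n_predictors = 2, n_max = 100000) {
  if (f2 <= 0) stopf("f2 must be > 0")
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stopf("alpha and power must lie in (0, 1)")
  }
  for (n in (n_predictors + 2):n_max) {
    pw <- regression_power(n, f2, alpha, n_predictors)
    if (pw >= power) return(list(n = n, achieved_power = pw))
  }
  stopf("target power unreachable below n = %d", n_max)
}

#' Intraclass correlation ICC(2,1)
#'
#' Single-rater, two-way random-effects intraclass correlation from the
#' ANOVA mean squares: `(MSR - MSE) / (MSR + (k-1) MSE + (k/n)(MSC - MSE))`
#' with MSR the between-subject, MSC the between-rater and MSE the
#' residual mean square.
#'
#' @param ratings Numeric matrix, subjects x raters, no missing cells.
#' @return The ICC(2,1) estimate.
#' @export
icc2 <- function(ratings) {
  m <- as.matrix(ratings)
  n <- nrow(m); k <- ncol(m)
  if (k < 2) stopf("need >= 2 raters")
  if (n < 3) stopf("need >= 3 subjects")
  if (any(!is.finite(m))) stopf("ratings must be complete and finite")
  grand <- mean(m)
  if (sum((m - grand)^2) == 0) stopf("zero total variance in ratings")
  msr <- k * sum((rowMeans(m) - grand)^2) / (n - 1)
  msc <- n * sum((colMeans(m) - grand)^2) / (k - 1)
  sse <- sum((m - outer(rowMeans(m), rep(1, k)) -
                outer(rep(1, n), colMeans(m)) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Majority vote over three reader calls
#'
#' @param calls Length-3 binary vector, or an n x 3 matrix of calls.
#' @return Binary vote(s): positive iff at least two calls are positive.
#' @export
majority_vote <- function(calls) {
  m <- if (is.matrix(calls)) calls else matrix(calls, nrow = 1)
  if (ncol(m) != 3) stopf("exactly 3 reader calls are required")
  if (any(is.na(m)) || !all(m %in% c(0, 1))) stopf("calls must be binary and complete")
  as.integer(rowSums(m) >= 2)
}
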