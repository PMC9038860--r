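test_that("the bounded logit compression matches its closed form", {
  expect_equal(logit_bounded(0.5, 35), 0)
  expect_equal(logit_bounded(0, 35), qlogis(0.5 / 35))
  expect_equal(logit_bounded(0, 35), -4.234107, tolerance = 1e-6)
  expect_equal(logit_bounded(1, 35), -logit_bounded(0, 35))  # antisymmetry
  expect_error(logit_bounded(0.5, 1), ">= 2")
  expect_error(logit_bounded(1.2, 10), "\\[0, 1\\]")
})

test_that("the regression recovers a known slope on a standardized predictor", {
  ok <- vapply(1:20, function(s) {
    fit <- fit_infiltration_model(simulate_cohort_df(0.8, 200, 400 + s))
    slope <- fit$coefficients$estimate[fit$coefficients$term == "non_fatty_percent"]
    abs(slope - 0.8) < 0.15
  }, TRUE)
  expect_gte(sum(ok), 17)  # the band holds for ~95% of seeds
})

test_that("a duplicated predictor raises a rank-deficiency error", {
  d <- simulate_cohort_df(0.5, 40, 1)
  d$bmd_mg_ml <- 2 * d$non_fatty_percent
  expect_error(fit_infiltration_model(d), "rank-deficient")
})

test_that("too few complete cases is an error", {
  d <- simulate_cohort_df(0.5, 8, 1)
  expect_error(fit_infiltration_model(d), "at least 10")
})

test_that("HC0 covariance equals the textbook sandwich on a 5-point fixture", {
  d <- tibble::tibble(infiltration = c(0.05, 0.2, 0.45, 0.7, 0.9),
                      non_fatty_percent = c(1, 3, 2, 8, 7),
                      bmd_mg_ml = c(80, 95, 100, 110, 90))
  fit <- fit_infiltration_model(d, min_n = 5)
  X <- stats::model.matrix(fit$fit)
  e <- stats::residuals(fit$fit)
  bread <- solve(crossprod(X))
  hand <- bread %*% t(X) %*% diag(e^2) %*% X %*% bread
  expect_lt(max(abs(fit$vcov_hc0 - hand)) / max(abs(hand)), 1e-10)
})

test_that("Breusch-Pagan equals the brute-force auxiliary regression", {
  set.seed(3)
  x1 <- c(1, 2, 3, 4); u <- c(0.5, -1, 2, -0.3)
  bp <- breusch_pagan(cbind(x = x1), u)
  aux <- stats::lm(I(u^2) ~ x1)
  expect_equal(bp$statistic, 4 * summary(aux)$r.squared)
  expect_equal(bp$df, 1)
  # larger fixture against lmtest's studentized version
  n <- 120
  x <- cbind(a = rnorm(n), b = runif(n))
  y <- 1 + x[, 1] - 0.5 * x[, 2] + rnorm(n, 0, 1 + 0.5 * abs(x[, 1]))
  f <- stats::lm(y ~ x)
  bp2 <- breusch_pagan(x, stats::residuals(f))
  ref <- lmtest::bptest(f)
  expect_equal(bp2$statistic, unname(ref$statistic), tolerance = 1e-9)
  expect_equal(bp2$p_value, unname(ref$p.value), tolerance = 1e-9)
  # constant residuals degenerate cleanly
  expect_equal(breusch_pagan(cbind(x1), rep(2, 4)),
               list(statistic = 0, p_value = 1, df = 1))
})

test_that("Breusch-Pagan has correct size and detects variance trends", {
  reps <- 400
  n <- 500
  rej_null <- rej_alt <- logical(reps)
  for (r in seq_len(reps)) {
    set.seed(9000 + r)
    x <- runif(n, 1, 3)
    X <- cbind(1, x)
    y0 <- 2 + x + rnorm(n)
    u0 <- stats::lm.fit(X, y0)$residuals
    rej_null[r] <- breusch_pagan(cbind(x), u0)$p_value < 0.05
    y1 <- 2 + x + rnorm(n, 0, sqrt(x))
    u1 <- stats::lm.fit(X, y1)$residuals
    rej_alt[r] <- breusch_pagan(cbind(x), u1)$p_value < 0.05
  }
  expect_lt(abs(mean(rej_null) - 0.05), 0.03)
  expect_gt(mean(rej_alt), 0.9)
})

test_that("regression power and sample size follow the noncentral-F oracle", {
  # independent oracle: direct noncentral-F enumeration
  oracle_n <- local({
    n <- 4
    repeat {
      pw <- 1 - stats::pf(stats::qf(0.95, 1, n - 3), 1, n - 3, ncp = 0.32 * n)
      if (pw >= 0.8) break
      n <- n + 1
    }
    n
  })
  res <- regression_sample_size(f2 = 0.32, alpha = 0.05, power = 0.8, n_predictors = 2)
  expect_equal(res$n, oracle_n)
  expect_gte(res$achieved_power, 0.8)
  # monotonicity: doubling f2 never increases required n
  for (f2 in c(0.05, 0.15, 0.32)) {
    expect_lte(regression_sample_size(2 * f2)$n, regression_sample_size(f2)$n)
  }
  # enormous effects need only n_predictors + 2 observations
  expect_equal(regression_sample_size(f2 = 1e6)$n, 4)
})

test_that("ICC(2,1) matches a hand ANOVA on a 6x2 table and behaves at the limits", {
  m <- matrix(c(9, 2, 5, 8, 6, 7,
                10, 4, 6, 9, 7, 8), ncol = 2)
  # hand-computed two-way ANOVA mean squares
  n <- 6; k <- 2
  grand <- mean(m)
  ssr <- k * sum((rowMeans(m) - grand)^2)
  ssc <- n * sum((colMeans(m) - grand)^2)
  sst <- sum((m - grand)^2)
  msr <- ssr / (n - 1); msc <- ssc / (k - 1)
  mse <- (sst - ssr - ssc) / ((n - 1) * (k - 1))
  hand <- (msr - mse) / (msr + (k - 1) * mse + k / n * (msc - mse))
  expect_equal(icc2(m), hand)
  # identical raters agree perfectly
  expect_equal(icc2(cbind(1:10, 1:10)), 1)
  # independent noise has near-zero ICC
  set.seed(5)
  expect_lt(abs(icc2(cbind(rnorm(200), rnorm(200)))), 0.15)
  expect_error(icc2(matrix(1, 5, 2)), "zero total variance")
  expect_error(icc2(matrix(1:4, 2, 2)), ">= 3 subjects")
})

test_that("empirical power of the classical main-predictor test matches noncentral-F", {
  # fixed-noncentrality design: the predictor is orthogonalized against the
  # covariate and scaled so the noncentrality is exactly f2 * n, which is
  # the model the noncentral-F power function describes
  n <- 35; f2 <- 0.32
  rej <- vapply(1:2000, function(s) {
    set.seed(50000 + s)
    bmd <- rnorm(n, 97, 15)
    x <- rnorm(n)
    xt <- stats::residuals(stats::lm(x ~ bmd))
    xt <- xt / sqrt(sum(xt^2) / n)
    lat <- sqrt(f2) * xt + rnorm(n)
    infl <- pmin(pmax((plogis(lat) * n - 0.5) / (n - 1), 0), 1)
    fit <- fit_infiltration_model(tibble::tibble(infiltration = infl,
                                                 non_fatty_percent = xt,
                                                 bmd_mg_ml = bmd))
    fit$coefficients$p_value_classical[2] < 0.05
  }, TRUE)
  expect_lt(abs(mean(rej) - regression_power(n, f2)), 0.05)
})

test_that("majority vote requires two of three positive calls", {
  expect_equal(majority_vote(c(1, 1, 0)), 1L)
  expect_equal(majority_vote(c(0, 0, 0)), 0L)
  expect_equal(majority_vote(c(1, 0, 0)), 0L)
  expect_equal(majority_vote(rbind(c(1, 1, 1), c(0, 1, 1), c(0, 0, 1))),
               c(1L, 1L, 0L))
  expect_error(majority_vote(c(1, 0)), "exactly 3")
  expect_error(majority_vote(c(1, NA, 0)), "binary and complete")
})
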