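test_that("calibration-in-the-large matches the closed-form constant-offset MLE", {
  # with a constant offset, the offset-logistic MLE is logit(ybar) - lp
  y <- rep(c(1, 0), c(25, 75))
  p <- rep(0.5, 100)
  res <- calibration_in_the_large(p, y)
  expect_equal(res$estimate, log(1 / 3), tolerance = 1e-6)
  expect_equal(res$mean_predicted, 0.5)
  expect_equal(res$mean_observed, 0.25)
  expect_lt(res$ci[["lower"]], res$estimate)
  expect_gt(res$ci[["upper"]], res$estimate)

  # predictions uniformly above the event rate give a negative intercept
  expect_lt(calibration_in_the_large(rep(0.6, 100), y)$estimate, 0)
  # and uniformly below, a positive one
  expect_gt(calibration_in_the_large(rep(0.1, 100), y)$estimate, 0)

  # perfectly calibrated limit: intercept near zero
  set.seed(11)
  p2 <- runif(40000, 0.05, 0.6)
  y2 <- rbinom(length(p2), 1, p2)
  expect_equal(calibration_in_the_large(p2, y2)$estimate, 0,
               tolerance = 0.05)

  expect_error(calibration_in_the_large(rep(0.5, 5), rep(1, 5)),
               class = "csdh_metric_error")
})

test_that("calibration slope recovers the generating coefficient", {
  set.seed(21)
  p <- expit(rnorm(100000, -2, 1))
  lp <- logit(p)
  y1 <- rbinom(length(p), 1, expit(lp))
  expect_equal(calibration_slope(p, y1)$estimate, 1, tolerance = 0.03)
  # underfitting: outcomes generated from 2*lp give slope near 2
  y2 <- rbinom(length(p), 1, expit(2 * lp))
  expect_equal(calibration_slope(p, y2)$estimate, 2, tolerance = 0.1)
  # no association: coin-flip outcomes give slope near 0
  y0 <- rbinom(length(p), 1, 0.3)
  expect_equal(calibration_slope(p, y0)$estimate, 0, tolerance = 0.05)
  # constant linear predictor: slope undefined
  expect_error(calibration_slope(rep(0.4, 50), rbinom(50, 1, 0.4)),
               class = "csdh_metric_error")
})

test_that("concordance handles separation, ties, and matches survival::concordance", {
  expect_equal(concordance_index(c(0.2, 0.8), c(0, 1), ci = FALSE)$estimate, 1)
  expect_equal(concordance_index(c(0.8, 0.2), c(0, 1), ci = FALSE)$estimate, 0)
  # all-tied predictions: C = 0.5 by the half-credit convention
  expect_equal(
    concordance_index(rep(0.3, 40), rep(c(0, 1), 20), ci = FALSE)$estimate,
    0.5)
  expect_error(concordance_index(runif(5), rep(1, 5)),
               class = "csdh_metric_error")

  set.seed(31)
  p <- 0.05 + 0.9 * round(runif(400), 2)  # rounding forces ties
  y <- rbinom(400, 1, p)
  mine <- concordance_index(p, y, ci = FALSE)$estimate
  sv <- survival::concordance(y ~ p)$concordance
  expect_equal(mine, sv, tolerance = 1e-12)
})

test_that("bootstrap interval brackets the estimate and is seed-reproducible", {
  set.seed(5)
  p <- runif(300, 0.05, 0.9)
  y <- rbinom(300, 1, p)
  a <- concordance_index(p, y, boot = 300, seed = 9)
  b <- concordance_index(p, y, boot = 300, seed = 9)
  expect_identical(a, b)
  expect_lte(a$ci[["lower"]], a$estimate)
  expect_gte(a$ci[["upper"]], a$estimate)
  expect_gt(a$boot_var_logit, 0)
})

test_that("model-based concordance matches its closed forms", {
  # single pair: (0.8*0.8) / (0.8*0.8 + 0.2*0.2)
  expect_equal(model_based_concordance(c(0.2, 0.8)), 0.64 / 0.68,
               tolerance = 1e-12)
  # identical predictions: everything tied, mbc = 0.5
  expect_equal(model_based_concordance(rep(0.37, 50)), 0.5,
               tolerance = 1e-12)
  expect_error(model_based_concordance(0.4), class = "csdh_metric_error")
})

test_that("optimized C and mbc agree exactly with O(n^2) brute force", {
  set.seed(99)
  for (rep in 1:25) {
    n <- sample(5:120, 1)
    p <- if (rep %% 3 == 0) round(runif(n), 1) else runif(n)
    p <- clip_prob(p)
    y <- rbinom(n, 1, 0.4)
    if (sum(y) == 0) y[1] <- 1
    if (sum(y) == n) y[1] <- 0
    expect_equal(concordance_index(p, y, ci = FALSE)$estimate,
                 brute_concordance(p, y), tolerance = 1e-12)
    expect_equal(model_based_concordance(p), brute_mbc(p),
                 tolerance = 1e-12)
  }
})

test_that("C is rank-invariant, mbc is not; permuting y moves C not mbc", {
  set.seed(42)
  p <- runif(250, 0.02, 0.95)
  y <- rbinom(250, 1, p)
  c0 <- concordance_index(p, y, ci = FALSE)$estimate
  # strictly increasing transform leaves C unchanged...
  expect_equal(concordance_index(p^2, y, ci = FALSE)$estimate, c0,
               tolerance = 1e-12)
  # ...but changes mbc (it reads the probabilities as probabilities)
  expect_gt(abs(model_based_concordance(p^2) - model_based_concordance(p)),
            0.01)
  # permuting outcomes drives C to chance (mbc takes no outcomes at all)
  yp <- sample(y)
  cp <- concordance_index(p, yp, ci = FALSE)$estimate
  expect_lt(abs(cp - 0.5), 0.08)
})

test_that("mbc is the expected C under a correct model", {
  set.seed(77)
  p <- expit(rnorm(60000, -1.5, 1.2))
  y <- rbinom(length(p), 1, p)
  C <- concordance_index(p, y, ci = FALSE)$estimate
  expect_equal(C, model_based_concordance(p), tolerance = 0.01)
})

test_that("calibration curves bin by predicted risk with equal counts", {
  set.seed(3)
  p <- runif(1000, 0.05, 0.95)
  y <- rbinom(1000, 1, p)
  cc <- calibration_curve(p, y)
  expect_equal(cc$n, rep(100L, 10))
  expect_equal(sum(cc$n), 1000L)
  expect_true(all(cc$observed >= 0 & cc$observed <= 1))
  # calibrated data: bins hug the diagonal
  expect_lt(max(abs(cc$observed - cc$mean_predicted)), 0.15)
  # predictions shifted upward: curve falls below the diagonal
  ps <- clip_prob(p + 0.1)
  cs <- calibration_curve(ps, y)
  expect_true(mean(cs$observed - cs$mean_predicted) < -0.05)
  # fewer distinct predictions than bins: reduced-bin fallback, flagged
  pf <- rep(c(0.2, 0.4, 0.6), length.out = 300)
  cf <- calibration_curve(pf, rbinom(300, 1, pf))
  expect_true(attr(cf, "reduced_bins"))
  expect_equal(nrow(cf), 3L)
  # smoother variant returns a curve over the prediction range
  sm <- calibration_curve(p, y, method = "smoother")
  expect_identical(attr(sm, "method"), "smoother")
  expect_true(all(diff(sm$p) >= 0))
})

test_that("validate_predictions bundles all statistics coherently", {
  set.seed(8)
  p <- runif(500, 0.05, 0.9)
  y <- rbinom(500, 1, p)
  res <- validate_predictions(p, y, boot = 200, seed = 2)
  expect_s3_class(res, "csdh_validation")
  expect_equal(res$n, 500L)
  expect_equal(res$events, sum(y))
  expect_equal(res$mean_observed, mean(y))
  expect_equal(res$mbc, model_based_concordance(p))
  expect_lte(res$intercept$ci[["lower"]], res$intercept$estimate)
  expect_gte(res$slope$ci[["upper"]], res$slope$estimate)
})
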