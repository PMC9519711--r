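test_that("Rubin pooling reproduces hand-computed combinations", {
  # degenerate: identical estimates, B = 0, T = W
  r0 <- rubin_pool(c(1, 1, 1), c(4, 4, 4))
  expect_equal(r0$estimate, 1)
  expect_equal(r0$W, 4)
  expect_equal(r0$B, 0)
  expect_equal(r0$Total, 4)

  # hand computation: m=2, estimates {0,2}, variances {1,1}
  r1 <- rubin_pool(c(0, 2), c(1, 1))
  expect_equal(r1$estimate, 1)
  expect_equal(r1$W, 1)
  expect_equal(r1$B, 2)
  expect_equal(r1$Total, 1 + 1.5 * 2)

  # permutation invariance
  set.seed(4)
  est <- rnorm(8); va <- runif(8, 0.5, 2)
  o <- sample(8)
  a <- rubin_pool(est, va); b <- rubin_pool(est[o], va[o])
  expect_equal(a$estimate, b$estimate)
  expect_equal(a$Total, b$Total)

  # T >= W always
  expect_gte(a$Total, a$W)
  expect_error(rubin_pool(1, 1), class = "csdh_mi_error")
  expect_error(rubin_pool(c(1, 2), c(1, -1)), class = "csdh_mi_error")

  # Barnard-Rubin df never exceeds the large-sample df
  rb <- rubin_pool(c(0, 2, 1), c(1, 1, 1), dfcom = 50)
  rl <- rubin_pool(c(0, 2, 1), c(1, 1, 1))
  expect_lte(rb$df, rl$df)
})

test_that("a cohort with no missing cells yields m identical copies", {
  cfg <- synthetic_config(n = 150, seed = 3)
  coh <- simulate_cohort(cfg, missingness = FALSE)
  st <- impute_chained(coh, imputation_config(m = 3, maxit = 2, seed = 1))
  expect_length(st$completed, 3L)
  expect_identical(st$completed[[1]], coh)
  expect_identical(st$completed[[2]], st$completed[[3]])
  expect_false(any(st$where))
})

test_that("imputation fills every predictor cell and never touches observed data", {
  cfg <- synthetic_config(n = 350, seed = 19)
  coh <- simulate_cohort(cfg)
  st <- impute_chained(coh, imputation_config(m = 2, maxit = 3, seed = 8))
  for (j in 1:2) {
    d <- complete_data(st, j)
    for (v in st$imputed_vars) {
      expect_false(anyNA(d[[v]]))
      obs <- !is.na(coh[[v]])
      expect_identical(d[[v]][obs], coh[[v]][obs])
    }
    # outcomes were never imputed: missing cells stay missing
    expect_identical(is.na(d$mortality_30d), is.na(coh$mortality_30d))
    expect_identical(is.na(d$recurrence_3m), is.na(coh$recurrence_3m))
  }
})

test_that("same seed and config give an identical stack", {
  cfg <- synthetic_config(n = 200, seed = 23)
  coh <- simulate_cohort(cfg)
  s1 <- impute_chained(coh, imputation_config(m = 2, maxit = 2, seed = 77))
  s2 <- impute_chained(coh, imputation_config(m = 2, maxit = 2, seed = 77))
  expect_identical(s1$completed, s2$completed)
  s3 <- impute_chained(coh, imputation_config(m = 2, maxit = 2, seed = 78))
  expect_false(identical(s1$completed, s3$completed))
})

test_that("a variable missing for one whole region is imputed from the others", {
  cfg <- synthetic_config(
    n = 500, seed = 31,
    missing_rates = c(volume_ml = 0.1),
    structural_missing = list(list(region = "Amsterdam",
                                   column = "hypertension")))
  coh <- simulate_cohort(cfg)
  ams <- coh$region == "Amsterdam"
  expect_true(all(is.na(coh$hypertension[ams])))
  expect_true(any(!is.na(coh$hypertension[!ams])))
  st <- impute_chained(coh, imputation_config(m = 2, maxit = 3, seed = 2))
  d <- complete_data(st, 1)
  expect_false(anyNA(d$hypertension))
  expect_true(is.logical(d$hypertension))
})

test_that("a variable missing everywhere is rejected as unimputable", {
  coh <- simulate_cohort(synthetic_config(n = 80, seed = 5),
                         missingness = FALSE)
  coh$volume_ml <- NA_real_
  expect_error(impute_chained(coh, imputation_config(m = 2, seed = 1)),
               "volume_ml", class = "csdh_unimputable")
})

test_that("MCAR imputation preserves the variable's distribution", {
  set.seed(55)
  n <- 5000
  x2 <- rnorm(n)
  x1 <- 0.6 * x2 + rnorm(n, sd = 0.8) + 5
  d <- data.frame(patient_id = as.character(1:n), x1 = x1, x2 = x2,
                  region = sample(c("Amsterdam", "North-East", "Rotterdam"),
                                  n, TRUE),
                  mortality_30d = rbinom(n, 1, 0.1) == 1)
  full_mean <- mean(d$x1)
  d_miss <- d
  d_miss$x1[runif(n) < 0.2] <- NA
  st <- impute_chained(d_miss, imputation_config(m = 5, maxit = 3, seed = 6))
  means <- vapply(st$completed, function(dd) mean(dd$x1), 0)
  # completed-data mean within Monte-Carlo tolerance of the full-data mean
  expect_lt(abs(mean(means) - full_mean), 0.05)
})

test_that("pooled validation over a degenerate stack equals the single run", {
  cfg <- synthetic_config(n = 400, seed = 9)
  coh <- simulate_cohort(cfg, missingness = FALSE)
  st <- impute_chained(coh, imputation_config(m = 3, maxit = 1, seed = 1))
  spec <- read_model_spec(shipped_model_files()[["jack_synthetic"]])
  pooled <- pool_validation(st, spec, boot = 150, seed = 13)
  single <- validate_predictions(predict_risk(coh, spec)$p,
                                 coh$recurrence_2m, boot = 150, seed = 13)
  expect_equal(pooled$intercept$estimate, single$intercept$estimate)
  expect_equal(pooled$slope$estimate, single$slope$estimate)
  expect_equal(pooled$intercept$pooled$B, 0)
  expect_equal(pooled$mbc, single$mbc)
  expect_equal(pooled$c_index$estimate, single$c_index$estimate,
               tolerance = 1e-10)
})
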