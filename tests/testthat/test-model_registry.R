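test_that("shipped model definitions load with the published structure", {
  specs <- lapply(shipped_model_files(), read_model_spec)
  expect_length(specs, 4L)

  alford <- specs$alford_she_synthetic
  expect_s3_class(alford, "csdh_model_spec")
  expect_identical(alford$outcome, "mortality_30d")
  expect_identical(alford$target_population, "age > 65")
  expect_setequal(model_fields(alford),
                  c("age", "gcs_category", "volume_ml"))

  jack <- specs$jack_synthetic
  expect_identical(jack$outcome, "recurrence_2m")
  expect_setequal(model_fields(jack), c("age", "volume_ml", "septations"))

  expect_identical(specs$andersen_a_synthetic$outcome, "recurrence_3m")
  expect_setequal(
    model_fields(specs$andersen_a_synthetic),
    c("volume_ml", "density", "hypertension", "drainage_time",
      "drain_type", "postop_complication"))
  expect_setequal(model_fields(specs$andersen_b_synthetic),
                  c("volume_ml", "density", "hypertension"))
})

test_that("malformed definitions are rejected with the offending field", {
  # probability outside (0,1)
  bad_prob <- write_model_yaml(c(
    "name: bad", "outcome: mortality_30d",
    "predictors:",
    "  - field: age", "    kind: threshold_category",
    "    categories:",
    "      - {upper: 80, upper_inclusive: false, points: 0}",
    "      - {lower: 80, lower_inclusive: true, points: 1}",
    "risk_map:",
    "  kind: score_table",
    "  table:",
    "    - {score: 0, probability: 0.5}",
    "    - {score: 1, probability: 1.2}"))
  expect_error(read_model_spec(bad_prob), "risk_map",
               class = "csdh_validation_error")

  # age categories {<80, >80}: 80 itself uncovered
  gap <- write_model_yaml(c(
    "name: gap", "outcome: mortality_30d",
    "predictors:",
    "  - field: age", "    kind: threshold_category",
    "    categories:",
    "      - {upper: 80, upper_inclusive: false, points: 0}",
    "      - {lower: 80, lower_inclusive: false, points: 1}",
    "risk_map:",
    "  kind: score_table",
    "  table:",
    "    - {score: 0, probability: 0.1}",
    "    - {score: 1, probability: 0.2}"))
  expect_error(read_model_spec(gap), "exhaustive",
               class = "csdh_validation_error")

  # non-monotone risk map
  nonmono <- write_model_yaml(c(
    "name: nm", "outcome: mortality_30d",
    "predictors:",
    "  - field: age", "    kind: threshold_category",
    "    categories:",
    "      - {upper: 80, upper_inclusive: false, points: 0}",
    "      - {lower: 80, lower_inclusive: true, points: 1}",
    "risk_map:",
    "  kind: score_table",
    "  table:",
    "    - {score: 0, probability: 0.3}",
    "    - {score: 1, probability: 0.2}"))
  expect_error(read_model_spec(nonmono), "monotone",
               class = "csdh_validation_error")

  # achievable score missing from the table
  uncovered <- write_model_yaml(c(
    "name: uc", "outcome: mortality_30d",
    "predictors:",
    "  - field: age", "    kind: threshold_category",
    "    categories:",
    "      - {upper: 80, upper_inclusive: false, points: 0}",
    "      - {lower: 80, lower_inclusive: true, points: 2}",
    "risk_map:",
    "  kind: score_table",
    "  table:",
    "    - {score: 0, probability: 0.1}",
    "    - {score: 1, probability: 0.2}"))
  expect_error(read_model_spec(uncovered), "not covered",
               class = "csdh_validation_error")

  expect_error(read_model_spec(tempfile()), class = "csdh_load_error")
})

test_that("boundary encodings distinguish '< 80 vs >= 80' from '<= 80 vs > 80'", {
  alford <- read_model_spec(shipped_model_files()[["alford_she_synthetic"]])
  jack <- read_model_spec(shipped_model_files()[["jack_synthetic"]])
  at80_alford <- data.frame(age = 80, gcs_category = "13-15",
                            volume_ml = 40)
  at80_jack <- data.frame(age = 80, volume_ml = 40, septations = FALSE)
  # age 80 carries the upper category's point under the SHE encoding...
  expect_identical(evaluate_score(at80_alford, alford), 1)
  # ...but the lower category's zero under the Jack encoding
  expect_identical(evaluate_score(at80_jack, jack), 0)
  # strictly beyond the boundary both agree
  at81 <- within(at80_alford, age <- 81)
  expect_identical(evaluate_score(at81, alford), 1)
  expect_identical(evaluate_score(within(at80_jack, age <- 81), jack), 1)
})

test_that("scores equal the exhaustively hand-summed category table", {
  spec <- toy_score_spec(age_pts = c(0, 2), gcs_pts = c(1, 3, 4),
                         vol_pts = c(0, 5))
  grid <- expand.grid(age = c(70, 85), gcs_category = c("13-15", "5-12", "3-4"),
                      volume_ml = c(30, 60), stringsAsFactors = FALSE)
  expected <- ifelse(grid$age >= 80, 2, 0) +
    c("13-15" = 1, "5-12" = 3, "3-4" = 4)[grid$gcs_category] +
    ifelse(grid$volume_ml >= 50, 5, 0)
  expect_equal(evaluate_score(grid, spec), unname(expected))

  # all-reference-category record scores zero
  ref <- data.frame(age = 70, gcs_category = "13-15", volume_ml = 40)
  expect_identical(evaluate_score(ref, toy_score_spec()), 0)
})

test_that("missing predictors raise an explicit error unless NA requested", {
  spec <- toy_score_spec()
  rec <- data.frame(age = 70, gcs_category = NA_character_, volume_ml = 40)
  expect_error(evaluate_score(rec, spec), class = "csdh_missing_predictor")
  expect_true(is.na(evaluate_score(rec, spec, on_missing = "na")))
  expect_error(predict_risk(rec, spec), class = "csdh_missing_predictor")
})

test_that("nomogram point axes interpolate linearly and clamp at extremes", {
  spec <- read_model_spec(shipped_model_files()[["andersen_b_synthetic"]])
  base <- data.frame(density = "homogeneous", hypertension = FALSE)
  pts <- function(v)
    evaluate_nomogram_points(cbind(base, volume_ml = v), spec)
  # exactly at an anchor: the anchor's points
  expect_equal(pts(50), 30)
  expect_equal(pts(150), 70)
  # midpoint between anchors: arithmetic mean of the two anchors' points
  expect_equal(pts(100), (30 + 70) / 2)
  expect_equal(pts(225), (70 + 100) / 2)
  # beyond the largest anchor: clamped
  expect_equal(pts(400), 100)
  expect_equal(pts(1000), pts(300))
  # cross-check against the reference interpolation routine
  vv <- c(10, 37.5, 62, 149.9, 260, 301)
  expect_equal(vapply(vv, pts, 0),
               approx(c(0, 50, 150, 300), c(0, 30, 70, 100), xout = vv,
                      rule = 2)$y)
})

test_that("predicted probability comes from the risk map and lp from clipped p", {
  spec <- toy_score_spec(probs = c(0.03, 0.10, 0.2, 0.3, 0.4, 0.5))
  rec <- data.frame(age = 70, gcs_category = "13-15", volume_ml = 60)
  out <- predict_risk(rec, spec)  # score 1
  expect_equal(out$p, 0.10)
  expect_equal(out$lp, log(0.10 / 0.90))

  # constant risk map: lp = 0 for every patient
  const <- constant_risk_spec(0.5)
  grid <- expand.grid(age = c(70, 85), gcs_category = "5-12",
                      volume_ml = c(30, 60), stringsAsFactors = FALSE)
  expect_equal(predict_risk(grid, const)$lp, rep(0, 4))

  # degenerate map probability clipped before logit
  tiny <- toy_score_spec(probs = c(1e-9, 1e-8, 1e-7, 0.1, 0.2, 0.3))
  out <- predict_risk(data.frame(age = 70, gcs_category = "13-15",
                                 volume_ml = 40), tiny)
  expect_equal(out$p, 1e-6)
  expect_equal(out$lp, log(1e-6 / (1 - 1e-6)))
})

test_that("logit and inverse logit round-trip across the clipped range", {
  p <- c(1e-6, 1e-4, 0.01, 0.2, 0.5, 0.77, 0.999, 1 - 1e-6)
  expect_equal(expit(logit(p)), p, tolerance = 1e-12)
})

test_that("risk maps are monotone and evaluation is deterministic", {
  specs <- lapply(shipped_model_files(), read_model_spec)
  for (spec in specs) {
    expect_true(all(diff(spec$risk_map$prob) >= 0))
  }
  # fuzz: random achievable totals keep predictions monotone in total
  spec <- specs$andersen_b_synthetic
  set.seed(41)
  d <- data.frame(
    volume_ml = runif(300, 1, 400),
    density = sample(c("homogeneous", "membranous", "mixed", "separated"),
                     300, replace = TRUE),
    hypertension = sample(c(TRUE, FALSE), 300, replace = TRUE))
  out <- predict_risk(d, spec)
  o <- order(out$total)
  expect_true(all(diff(out$p[o]) >= -1e-12))
  # determinism: identical input, bit-identical output
  expect_identical(out, predict_risk(d, spec))
})
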