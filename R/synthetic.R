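# Synthetic cohort generation.  The generator emulates the registry-style
# marginal distributions of a three-region Dutch CSDH cohort (region mix,
# demographics, imaging and treatment categories, outcome prevalences),
# a configurable true logistic outcome model, and both completely-random
# and region-structured missingness, so every pipeline stage can be
# exercised without patient data.

#' Synthetic cohort configuration
#'
#' Defaults reproduce the marginal distributions of the registry cohort
#' the package targets: age ~ Normal(73.0, 12.4) truncated to 18--105
#' years, 73.5% male, hematoma volume ~ Normal(112.6, 54.5) mL truncated
#' to positive values, region mix 10.6/54.7/34.7% (Amsterdam/North-East/
#' Rotterdam), GCS category mix 0.2/11.8/87.9%, septations 37.2%,
#' hypertension 16.1%, density 52.3/34.4/0.4/12.8%, drainage time
#' 13.2/50.7/27.0/9.1%, drain type 22.6/36.9/40.5%, postoperative
#' complications 7.2%, treatment mix 7.3/47.2/42.8/2.7%, and outcome
#' prevalence targets 3.9% (30-day mortality), 8.9% (2-month recurrence),
#' 9.5% (3-month recurrence).  Predictors are drawn independently: the
#' marginals pin no joint distribution, and independence is the honest
#' default.
#'
#' The true outcome models are logistic in standardized age and volume
#' and a few category indicators, with documented arbitrary coefficients;
#' the intercept of each is solved numerically so the marginal prevalence
#' hits its target.
#'
#' @param n cohort size.
#' @param seed integer seed; all randomness derives from it.
#' @param region_probs,male_prob,age_mean,age_sd,volume_mean,volume_sd,
#'   gcs_probs,septations_prob,hypertension_prob,density_probs,
#'   drainage_time_probs,drain_type_probs,complication_prob,
#'   treatment_probs marginal parameters (see Details above for defaults).
#' @param mortality_coefs,recurrence_coefs named coefficient vectors of
#'   the true outcome models over the internal feature set (`age_z`,
#'   `volume_z`, `sex_male`, `gcs_5_12`, `gcs_lt5`, `septations`,
#'   `hypertension`, `density_membranous`, `density_mixed`,
#'   `density_separated`, `age_gt80`).
#' @param prevalence named targets for `mortality_30d` and
#'   `recurrence_3m`; `recurrence_2m` is carved out of `recurrence_3m`
#'   events at rate `recurrence_2m_share` so the 2-month event set nests
#'   inside the 3-month one.
#' @param recurrence_2m_share share of 3-month recurrences already
#'   present at 2 months (default 155/164, the ratio of the targeted
#'   event counts).
#' @param missing_rates named per-column MCAR missingness rates
#'   (defaults mirror the registry's missing-data shares).
#' @param outcome_missing_rates MCAR rates for outcome columns; the two
#'   recurrence outcomes share one mask (they are ascertained together).
#' @param structural_missing list of `list(region=, column=)` pairs:
#'   the column is blanked for the whole region (a variable not assessed
#'   in that region).
#' @return list of class `csdh_synth_config`.
#' @export
synthetic_config <- function(
    n = 1760L, seed = 1L,
    region_probs = c(Amsterdam = 0.106, `North-East` = 0.547,
                     Rotterdam = 0.347),
    male_prob = 0.735,
    age_mean = 73.0, age_sd = 12.4,
    volume_mean = 112.6, volume_sd = 54.5,
    gcs_probs = c(`3-4` = 0.002, `5-12` = 0.118, `13-15` = 0.879),
    septations_prob = 0.372,
    hypertension_prob = 0.161,
    density_probs = c(homogeneous = 0.523, membranous = 0.344,
                      mixed = 0.004, separated = 0.128),
    drainage_time_probs = c(no_drain = 0.132, `1-24h` = 0.507,
                            `24-48h` = 0.270, `>48h` = 0.091),
    drain_type_probs = c(no_drain = 0.226, subdural = 0.369,
                         `subgaleal_subperiosteal` = 0.405),
    complication_prob = 0.072,
    treatment_probs = c(wait_and_see = 0.073, surgery = 0.472,
                        surgery_plus_dexamethasone = 0.428,
                        dexamethasone = 0.027),
    mortality_coefs = c(age_z = 0.9, gcs_lt5 = 2.0, gcs_5_12 = 0.9,
                        volume_z = 0.3),
    recurrence_coefs = c(volume_z = 0.5, septations = 0.4,
                         hypertension = 0.3, age_gt80 = -0.3),
    prevalence = c(mortality_30d = 0.039, recurrence_3m = 0.095),
    recurrence_2m_share = 155 / 164,
    missing_rates = c(gcs_category = 0.065, volume_ml = 0.466,
                      septations = 0.488, hypertension = 0.229,
                      density = 0.454, drainage_time = 0.569,
                      drain_type = 0.749, postop_complication = 0.224),
    outcome_missing_rates = c(mortality_30d = 0.059, recurrence = 0.015),
    structural_missing = list()) {
  for (block in list(region_probs, gcs_probs, density_probs,
                     drainage_time_probs, drain_type_probs,
                     treatment_probs)) {
    if (any(block < 0) || any(block > 1))
      stop_csdh("csdh_config_error",
                "probability blocks must lie in [0, 1]")
    if (abs(sum(block) - 1) > 0.02)
      stop_csdh("csdh_config_error",
                "probability block must sum to 1 (got %.3f)", sum(block))
  }
  if (any(c(male_prob, septations_prob, hypertension_prob,
            complication_prob, missing_rates, outcome_missing_rates,
            recurrence_2m_share) < 0) ||
      any(c(male_prob, septations_prob, hypertension_prob,
            complication_prob, missing_rates, outcome_missing_rates,
            recurrence_2m_share) > 1))
    stop_csdh("csdh_config_error", "rates must lie in [0, 1]")
  structure(as.list(environment()), class = "csdh_synth_config")
}

renorm <- function(p) p / sum(p)

draw_cat <- function(n, probs) {
  names(probs)[sample.int(length(probs), n, replace = TRUE,
                          prob = renorm(probs))]
}

#' Generate a synthetic cohort (predictors only)
#'
#' Draws `n` patient records from the configured marginals.  Output is
#' deterministic under the configuration seed.
#'
#' @param config a [synthetic_config()].
#' @return cohort data frame (no outcomes, no missingness yet).
#' @export
generate_cohort <- function(config = synthetic_config()) {
  stopifnot(inherits(config, "csdh_synth_config"))
  n <- config$n
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(config$seed))
  empty_chr <- character(0); empty_num <- numeric(0); empty_lgl <- logical(0)
  if (n == 0L) {
    return(data.frame(patient_id = empty_chr, region = empty_chr,
                      treatment = empty_chr, age = empty_num,
                      sex = empty_chr, gcs_category = empty_chr,
                      volume_ml = empty_num, hematoma_type = empty_chr,
                      septations = empty_lgl, density = empty_chr,
                      hypertension = empty_lgl, drainage_time = empty_chr,
                      drain_type = empty_chr, postop_complication = empty_lgl,
                      laterality = empty_chr, stringsAsFactors = FALSE))
  }
  # the configured mean/sd are observed (post-truncation) marginals, so
  # the underlying normals are moment-matched to the truncated targets
  age_par <- truncnorm_params(config$age_mean, config$age_sd, 18, 105)
  vol_par <- truncnorm_params(config$volume_mean, config$volume_sd, 0, Inf)
  septations <- runif(n) < config$septations_prob
  # hematoma type kept consistent with the septation-derivation rule
  hematoma_type <- ifelse(
    septations,
    sample(c("trabecular", "membranous"), n, replace = TRUE),
    sample(c("homogeneous", "mixed", "separated", "laminar", "other"), n,
           replace = TRUE, prob = c(0.55, 0.05, 0.2, 0.1, 0.1)))
  data.frame(
    patient_id = sprintf("P%05d", seq_len(n)),
    region = draw_cat(n, config$region_probs),
    treatment = draw_cat(n, config$treatment_probs),
    age = rtruncnorm(n, age_par[["mean"]], age_par[["sd"]], 18, 105),
    sex = ifelse(runif(n) < config$male_prob, "male", "female"),
    gcs_category = draw_cat(n, config$gcs_probs),
    volume_ml = rtruncnorm(n, vol_par[["mean"]], vol_par[["sd"]], 0, Inf),
    hematoma_type = hematoma_type,
    septations = septations,
    density = draw_cat(n, config$density_probs),
    hypertension = runif(n) < config$hypertension_prob,
    drainage_time = draw_cat(n, config$drainage_time_probs),
    drain_type = draw_cat(n, config$drain_type_probs),
    postop_complication = runif(n) < config$complication_prob,
    laterality = "unilateral",
    stringsAsFactors = FALSE
  )
}

# internal feature matrix the true outcome models are written in
outcome_features <- function(cohort, config) {
  data.frame(
    age_z = (cohort$age - config$age_mean) / config$age_sd,
    volume_z = (cohort$volume_ml - config$volume_mean) / config$volume_sd,
    sex_male = as.numeric(cohort$sex == "male"),
    gcs_5_12 = as.numeric(cohort$gcs_category == "5-12"),
    gcs_lt5 = as.numeric(cohort$gcs_category == "3-4"),
    septations = as.numeric(cohort$septations),
    hypertension = as.numeric(cohort$hypertension),
    density_membranous = as.numeric(cohort$density == "membranous"),
    density_mixed = as.numeric(cohort$density == "mixed"),
    density_separated = as.numeric(cohort$density == "separated"),
    age_gt80 = as.numeric(cohort$age > 80)
  )
}

#' Linear predictor of a true synthetic outcome model
#'
#' @param cohort cohort data frame with complete predictors.
#' @param coefs named coefficient vector over the internal feature set
#'   (see [synthetic_config()]); the intercept is supplied separately.
#' @param config the generating [synthetic_config()] (for the
#'   standardization constants).
#' @return numeric linear predictor (no intercept).
#' @export
true_linear_predictor <- function(cohort, coefs,
                                  config = synthetic_config()) {
  feats <- outcome_features(cohort, config)
  bad <- setdiff(names(coefs), names(feats))
  if (length(bad))
    stop_csdh("csdh_config_error", "unknown coefficient name(s): %s",
              paste(bad, collapse = ", "))
  if (!length(coefs)) return(rep(0, nrow(cohort)))
  drop(as.matrix(feats[names(coefs)]) %*% coefs)
}

#' Solve a logistic intercept for a target marginal prevalence
#'
#' Finds `c` such that `mean(expit(c + lp))` equals the target to within
#' `tol`, by bisection.  With all coefficients zero this is exactly
#' `logit(target)`.
#'
#' @param lp linear predictor values (no intercept).
#' @param target desired marginal event probability, strictly in (0, 1).
#' @param tol prevalence tolerance (default 1e-3 as an absolute
#'   probability; the solver iterates well past it).
#' @return the intercept.
#' @export
solve_intercept <- function(lp, target, tol = 1e-3) {
  if (!is.finite(target) || target <= 0 || target >= 1)
    stop_csdh("csdh_config_error",
              "prevalence target must lie strictly in (0, 1)")
  f <- function(c) mean(expit(c + lp)) - target
  lo <- -40; hi <- 40
  if (f(lo) > 0 || f(hi) < 0)
    stop_csdh("csdh_config_error",
              "prevalence target %.4f unattainable for this cohort", target)
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
    if (abs(f(mid)) < tol / 10 && (hi - lo) < 1e-9) break
  }
  (lo + hi) / 2
}

#' Attach outcomes drawn from the true models
#'
#' Each outcome is Bernoulli with probability `expit(intercept + lp)`;
#' the intercept is solved so the expected marginal prevalence hits the
#' configured target.  The 2-month recurrence indicator is carved out of
#' 3-month events, so the 2-month event set is always nested within the
#' 3-month one.
#'
#' @param cohort complete-predictor cohort from [generate_cohort()].
#' @param config the generating [synthetic_config()].
#' @param seed optional seed override (defaults to a sub-seed of
#'   `config$seed`).
#' @return cohort with logical `mortality_30d`, `recurrence_2m`,
#'   `recurrence_3m` columns; solved intercepts in attribute
#'   `"intercepts"`.
#' @export
generate_outcomes <- function(cohort, config = synthetic_config(),
                              seed = NULL) {
  stopifnot(inherits(config, "csdh_synth_config"))
  if (!nrow(cohort)) {
    cohort$mortality_30d <- logical(0)
    cohort$recurrence_2m <- logical(0)
    cohort$recurrence_3m <- logical(0)
    return(cohort)
  }
  if (is.null(seed)) seed <- subseeds(config$seed, 3L)[2L]
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  lp_mort <- true_linear_predictor(cohort, config$mortality_coefs, config)
  lp_rec <- true_linear_predictor(cohort, config$recurrence_coefs, config)
  c_mort <- solve_intercept(lp_mort, config$prevalence[["mortality_30d"]])
  c_rec <- solve_intercept(lp_rec, config$prevalence[["recurrence_3m"]])
  cohort$mortality_30d <- runif(nrow(cohort)) < expit(c_mort + lp_mort)
  cohort$recurrence_3m <- runif(nrow(cohort)) < expit(c_rec + lp_rec)
  cohort$recurrence_2m <- cohort$recurrence_3m &
    (runif(nrow(cohort)) < config$recurrence_2m_share)
  attr(cohort, "intercepts") <- c(mortality_30d = c_mort,
                                  recurrence_3m = c_rec)
  cohort
}

#' Mask cells to emulate registry missingness
#'
#' Applies per-column MCAR masking at the configured rates, blanks whole
#' columns within a region for structural (not-assessed-there)
#' missingness, and masks outcomes at their own rates -- the two
#' recurrence outcomes share one mask.  `hematoma_type` is masked
#' wherever `septations` is, keeping the derivation rule consistent.
#'
#' @param cohort cohort with outcomes.
#' @param config the generating [synthetic_config()].
#' @param seed optional seed override.
#' @return cohort with `NA` cells.
#' @export
apply_missingness <- function(cohort, config = synthetic_config(),
                              seed = NULL) {
  stopifnot(inherits(config, "csdh_synth_config"))
  if (!nrow(cohort)) return(cohort)
  if (is.null(seed)) seed <- subseeds(config$seed, 3L)[3L]
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  n <- nrow(cohort)
  for (col in names(config$missing_rates)) {
    if (is.null(cohort[[col]])) next
    mask <- runif(n) < config$missing_rates[[col]]
    cohort[[col]][mask] <- NA
    if (col == "septations") cohort$hematoma_type[mask] <- NA
  }
  for (sm in config$structural_missing) {
    if (is.null(sm$region) || is.null(sm$column) ||
        !sm$region %in% REGIONS || is.null(cohort[[sm$column]]))
      stop_csdh("csdh_config_error",
                "structural_missing entries need a valid region and column")
    cohort[[sm$column]][cohort$region == sm$region] <- NA
  }
  # a predictor column with no observed value anywhere cannot be imputed
  pred_cols <- union(names(config$missing_rates),
                     vapply(config$structural_missing,
                            function(sm) sm$column, ""))
  dead <- pred_cols[vapply(pred_cols, function(cl)
    !is.null(cohort[[cl]]) && all(is.na(cohort[[cl]])), TRUE)]
  if (length(dead))
    stop_csdh("csdh_config_error",
              "missingness leaves no observed values in: %s",
              paste(dead, collapse = ", "))
  omr <- config$outcome_missing_rates
  if (!is.na(omr["mortality_30d"]) && omr[["mortality_30d"]] > 0)
    cohort$mortality_30d[runif(n) < omr[["mortality_30d"]]] <- NA
  if (!is.na(omr["recurrence"]) && omr[["recurrence"]] > 0) {
    mask <- runif(n) < omr[["recurrence"]]
    cohort$recurrence_2m[mask] <- NA
    cohort$recurrence_3m[mask] <- NA
  }
  cohort
}

#' Simulate a full synthetic cohort
#'
#' [generate_cohort()] + [generate_outcomes()] + [apply_missingness()]
#' in one call, fully determined by `config$seed`.
#'
#' @param config a [synthetic_config()].
#' @param missingness apply the configured missingness? Set `FALSE` for
#'   a complete-data cohort.
#' @return cohort data frame.
#' @export
simulate_cohort <- function(config = synthetic_config(),
                            missingness = TRUE) {
  cohort <- generate_cohort(config)
  cohort <- generate_outcomes(cohort, config)
  if (missingness) cohort <- apply_missingness(cohort, config)
  cohort
}
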