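# Model registry: published prognostic models represented as data and
# evaluated on patient records.  A model definition carries (i) predictor
# rules -- categorizations with explicit boundary inclusion, named
# categories, or a continuous nomogram point axis -- and (ii) a risk map
# from total score/points to predicted probability.  The engine itself
# contains no model coefficients: everything numeric comes from the
# definition file.

VALID_OUTCOMES <- c("mortality_30d", "recurrence_2m", "recurrence_3m")

#' Construct a model specification
#'
#' Builds and validates a `csdh_model_spec` from its components.  Most
#' users will call [read_model_spec()] on a YAML definition file instead.
#'
#' @param name model identifier.
#' @param outcome one of `"mortality_30d"`, `"recurrence_2m"`,
#'   `"recurrence_3m"`.
#' @param predictors list of predictor rules; each rule is a list with
#'   `field`, `kind` (one of `"threshold_category"`, `"named_category"`,
#'   `"linear_points"`) and either `categories` (threshold/named) or
#'   `anchors` (linear_points).  Threshold categories give `lower`/`upper`
#'   bounds with explicit `lower_inclusive`/`upper_inclusive` flags, so
#'   that e.g. age dichotomised at "< 80 vs >= 80" and at "<= 80 vs > 80"
#'   are distinct encodings.
#' @param risk_map list with `kind` (`"score_table"` or
#'   `"nomogram_curve"`) and `table` of `(score|points, probability)`
#'   rows.
#' @param target_population optional eligibility expression as a string,
#'   e.g. `"age > 65"`, evaluated against cohort columns.
#' @param source free-text citation for the model definition.
#' @return a validated object of class `csdh_model_spec`.
#' @seealso [read_model_spec()], [predict_risk()]
#' @export
model_spec <- function(name, outcome, predictors, risk_map,
                       target_population = NULL, source = NULL) {
  spec <- structure(
    list(name = name, outcome = outcome, predictors = predictors,
         risk_map = risk_map, target_population = target_population,
         source = source),
    class = "csdh_model_spec"
  )
  validate_model_spec(spec)
}

#' Read a model definition file
#'
#' Model definitions are YAML files with fields `name`, `outcome`,
#' optional `target_population`, `predictors`, `risk_map`, and `source`.
#' The file is validated on load: categories must be exhaustive and
#' non-overlapping, probabilities strictly inside (0, 1), and the risk
#' map monotone non-decreasing and covering every achievable total.
#'
#' @param path path to a YAML model definition.
#' @return a `csdh_model_spec`.
#' @export
read_model_spec <- function(path) {
  if (!file.exists(path))
    stop_csdh("csdh_load_error", "model definition file not found: %s", path)
  raw <- yaml::read_yaml(path)
  for (fld in c("name", "outcome", "predictors", "risk_map")) {
    if (is.null(raw[[fld]]))
      stop_csdh("csdh_load_error",
                "model definition '%s' is missing required field '%s'",
                path, fld)
  }
  model_spec(name = raw$name, outcome = raw$outcome,
             predictors = raw$predictors, risk_map = raw$risk_map,
             target_population = raw$target_population,
             source = raw$source)
}

#' Fields a model needs from a patient record
#'
#' @param spec a `csdh_model_spec`.
#' @return character vector of record field names.
#' @export
model_fields <- function(spec) {
  stopifnot(inherits(spec, "csdh_model_spec"))
  vapply(spec$predictors, `[[`, "", "field")
}

# ---- validation ------------------------------------------------------------

validate_model_spec <- function(spec) {
  if (!is.character(spec$name) || length(spec$name) != 1L)
    stop_csdh("csdh_validation_error", "field 'name': must be a single string")
  if (!spec$outcome %in% VALID_OUTCOMES)
    stop_csdh("csdh_validation_error",
              "field 'outcome': '%s' is not one of %s", spec$outcome,
              paste(VALID_OUTCOMES, collapse = ", "))
  if (length(spec$predictors) < 1L)
    stop_csdh("csdh_validation_error", "field 'predictors': empty")
  for (i in seq_along(spec$predictors))
    spec$predictors[[i]] <- validate_predictor_rule(spec$predictors[[i]], i)
  spec$risk_map <- validate_risk_map(spec$risk_map, spec$predictors)
  spec
}

validate_predictor_rule <- function(rule, idx) {
  if (is.null(rule$field) || is.null(rule$kind))
    stop_csdh("csdh_validation_error",
              "predictor %d: 'field' and 'kind' are required", idx)
  kinds <- c("threshold_category", "named_category", "linear_points")
  if (!rule$kind %in% kinds)
    stop_csdh("csdh_validation_error",
              "predictor '%s': unknown kind '%s'", rule$field, rule$kind)

  if (rule$kind == "linear_points") {
    a <- rule$anchors
    if (is.null(a) || length(a) < 2L)
      stop_csdh("csdh_validation_error",
                "predictor '%s': linear_points needs >= 2 anchors", rule$field)
    v <- vapply(a, function(x) as.numeric(x$value), 0)
    p <- vapply(a, function(x) as.numeric(x$points), 0)
    if (anyNA(v) || anyNA(p))
      stop_csdh("csdh_validation_error",
                "predictor '%s': anchors need numeric value and points",
                rule$field)
    o <- order(v)
    if (any(duplicated(v)))
      stop_csdh("csdh_validation_error",
                "predictor '%s': duplicate anchor values", rule$field)
    rule$anchor_value <- v[o]
    rule$anchor_points <- p[o]
    return(rule)
  }

  cats <- rule$categories
  if (is.null(cats) || length(cats) < 1L)
    stop_csdh("csdh_validation_error",
              "predictor '%s': no categories", rule$field)
  pts <- vapply(cats, function(x) as.numeric(x$points), 0)
  if (anyNA(pts))
    stop_csdh("csdh_validation_error",
              "predictor '%s': every category needs numeric points", rule$field)

  if (rule$kind == "named_category") {
    lv <- vapply(cats, function(x) norm_level(x$level), "")
    if (anyNA(lv) || any(!nzchar(lv)))
      stop_csdh("csdh_validation_error",
                "predictor '%s': every named category needs a level",
                rule$field)
    if (any(duplicated(lv)))
      stop_csdh("csdh_validation_error",
                "predictor '%s': duplicated category level", rule$field)
    rule$levels <- lv
    rule$points <- pts
    return(rule)
  }

  # threshold_category: the intervals must tile the whole real line with
  # complementary boundary inclusion -- {<80, >80} leaves 80 uncovered and
  # is rejected; {<80, >=80} and {<=80, >80} are both valid and distinct.
  iv <- lapply(cats, function(x) {
    list(lower = if (is.null(x$lower)) -Inf else as.numeric(x$lower),
         upper = if (is.null(x$upper)) Inf else as.numeric(x$upper),
         lower_inclusive = isTRUE(x$lower_inclusive),
         upper_inclusive = isTRUE(x$upper_inclusive))
  })
  o <- order(vapply(iv, `[[`, 0, "lower"), vapply(iv, `[[`, 0, "upper"))
  iv <- iv[o]
  pts <- pts[o]
  if (is.finite(iv[[1L]]$lower))
    stop_csdh("csdh_validation_error",
              "predictor '%s': lowest category must be unbounded below",
              rule$field)
  k <- length(iv)
  if (is.finite(iv[[k]]$upper))
    stop_csdh("csdh_validation_error",
              "predictor '%s': highest category must be unbounded above",
              rule$field)
  if (k > 1L) {
    for (j in seq_len(k - 1L)) {
      a <- iv[[j]]; b <- iv[[j + 1L]]
      if (!isTRUE(all.equal(a$upper, b$lower)) ||
          a$upper_inclusive == b$lower_inclusive)
        stop_csdh(
          "csdh_validation_error",
          paste0("predictor '%s': categories are not exhaustive and ",
                 "mutually exclusive at boundary %s"),
          rule$field, format(a$upper))
    }
  }
  rule$intervals <- iv
  rule$points <- pts
  rule
}

validate_risk_map <- function(rm, predictors) {
  if (is.null(rm$kind) || !rm$kind %in% c("score_table", "nomogram_curve"))
    stop_csdh("csdh_validation_error",
              "field 'risk_map': kind must be score_table or nomogram_curve")
  tab <- rm$table
  if (is.null(tab) || length(tab) < 1L)
    stop_csdh("csdh_validation_error", "field 'risk_map': empty table")
  key <- if (rm$kind == "score_table") "score" else "points"
  s <- vapply(tab, function(x) as.numeric(x[[key]]), 0)
  p <- vapply(tab, function(x) as.numeric(x$probability), 0)
  if (anyNA(s) || anyNA(p))
    stop_csdh("csdh_validation_error",
              "field 'risk_map': rows need %s and probability", key)
  if (any(p <= 0 | p >= 1))
    stop_csdh("csdh_validation_error",
              "field 'risk_map': probabilities must lie strictly in (0, 1)")
  o <- order(s)
  s <- s[o]; p <- p[o]
  if (any(duplicated(s)))
    stop_csdh("csdh_validation_error",
              "field 'risk_map': duplicated %s values", key)
  if (any(diff(p) < 0))
    stop_csdh("csdh_validation_error",
              "field 'risk_map': probability must be monotone non-decreasing")
  rm$key <- s
  rm$prob <- p

  # coverage: the achievable total must be representable by the map
  rng <- achievable_range(predictors)
  if (rm$kind == "score_table") {
    tot <- achievable_scores(predictors)
    missing <- setdiff(tot, s)
    if (length(missing))
      stop_csdh("csdh_validation_error",
                "field 'risk_map': achievable scores not covered: %s",
                paste(missing, collapse = ", "))
  } else {
    if (rng[1L] < min(s) - 1e-9 || rng[2L] > max(s) + 1e-9)
      stop_csdh("csdh_validation_error",
                paste0("field 'risk_map': achievable points [%g, %g] exceed ",
                       "the curve's range [%g, %g]"),
                rng[1L], rng[2L], min(s), max(s))
  }
  rm
}

predictor_point_range <- function(rule) {
  if (rule$kind == "linear_points") range(rule$anchor_points)
  else range(rule$points)
}

achievable_range <- function(predictors) {
  rngs <- vapply(predictors, predictor_point_range, numeric(2L))
  c(sum(rngs[1L, ]), sum(rngs[2L, ]))
}

achievable_scores <- function(predictors) {
  # all sums of one category's points per predictor (categorical rules only)
  tot <- 0
  for (rule in predictors) {
    if (rule$kind == "linear_points")
      stop_csdh("csdh_validation_error",
                "score_table risk map cannot combine with linear_points rule")
    tot <- unique(as.vector(outer(tot, rule$points, `+`)))
  }
  sort(tot)
}

norm_level <- function(x) tolower(trimws(as.character(x)))

# ---- evaluation ------------------------------------------------------------

# Points contributed by one predictor rule for a vector of field values.
rule_points <- function(rule, value) {
  out <- rep(NA_real_, length(value))
  if (rule$kind == "linear_points") {
    v <- as.numeric(value)
    ok <- !is.na(v)
    # piecewise-linear on the nomogram point axis, clamped at the
    # tabulated extremes (rule = 2)
    if (any(ok))
      out[ok] <- approx(rule$anchor_value, rule$anchor_points,
                        xout = v[ok], rule = 2, ties = "ordered")$y
    return(out)
  }
  if (rule$kind == "named_category") {
    idx <- match(norm_level(value), rule$levels)
    bad <- !is.na(value) & is.na(idx)
    if (any(bad))
      stop_csdh("csdh_domain_error",
                "predictor '%s': unknown category value '%s'",
                rule$field, as.character(value[bad][1L]))
    out <- rule$points[idx]
    return(out)
  }
  v <- as.numeric(value)
  ok <- !is.na(v)
  if (!any(ok)) return(out)
  for (j in seq_along(rule$intervals)) {
    iv <- rule$intervals[[j]]
    lo <- if (iv$lower_inclusive) v >= iv$lower else v > iv$lower
    hi <- if (iv$upper_inclusive) v <= iv$upper else v < iv$upper
    hit <- ok & lo & hi
    out[hit] <- rule$points[j]
  }
  out
}

total_points <- function(data, spec, on_missing = c("error", "na")) {
  on_missing <- match.arg(on_missing)
  data <- as.data.frame(data)
  tot <- rep(0, nrow(data))
  miss <- rep(FALSE, nrow(data))
  for (rule in spec$predictors) {
    if (is.null(data[[rule$field]]))
      stop_csdh("csdh_missing_predictor",
                "model '%s': cohort lacks column '%s'", spec$name, rule$field)
    pts <- rule_points(rule, data[[rule$field]])
    miss <- miss | is.na(pts)
    tot <- tot + pts
  }
  if (any(miss) && on_missing == "error")
    stop_csdh("csdh_missing_predictor",
              "model '%s': %d record(s) have missing predictor values",
              spec$name, sum(miss))
  tot
}

#' Total integer score of a score-based model
#'
#' Sums the per-category points of every predictor rule.  All predictors
#' must be non-missing; with `on_missing = "na"` missing records yield
#' `NA` instead of an error (the caller then decides between complete-case
#' exclusion and imputation).
#'
#' @param data a patient record (one-row data frame or list) or a cohort
#'   data frame.
#' @param spec a `csdh_model_spec` whose risk map is a `score_table`.
#' @param on_missing `"error"` (default) or `"na"`.
#' @return numeric vector of total scores.
#' @export
evaluate_score <- function(data, spec, on_missing = c("error", "na")) {
  stopifnot(inherits(spec, "csdh_model_spec"))
  total_points(data, spec, on_missing)
}

#' Total nomogram points of a nomogram-based model
#'
#' Categorical predictors contribute their category's points; continuous
#' predictors are read off the nomogram's point axis by piecewise-linear
#' interpolation between tabulated anchors, clamped at the extremes
#' (manual nomogram reading behaviour).
#'
#' @inheritParams evaluate_score
#' @return numeric vector of total points.
#' @export
evaluate_nomogram_points <- function(data, spec,
                                     on_missing = c("error", "na")) {
  stopifnot(inherits(spec, "csdh_model_spec"))
  total_points(data, spec, on_missing)
}

#' Predicted probability and linear predictor under a model
#'
#' Maps each record's total score/points through the model's risk map:
#' exact table lookup for `score_table`, monotone piecewise-linear
#' interpolation (clamped at the tabulated extremes) for
#' `nomogram_curve`.  Probabilities are clipped into `[1e-6, 1 - 1e-6]`
#' before the logit so the linear predictor is always finite.
#'
#' @inheritParams evaluate_score
#' @return data frame with columns `total` (score or points), `p`
#'   (predicted probability) and `lp` (its logit).
#' @export
predict_risk <- function(data, spec, on_missing = c("error", "na")) {
  stopifnot(inherits(spec, "csdh_model_spec"))
  tot <- total_points(data, spec, on_missing)
  rm <- spec$risk_map
  p <- rep(NA_real_, length(tot))
  ok <- !is.na(tot)
  if (any(ok)) {
    if (rm$kind == "score_table") {
      idx <- match(tot[ok], rm$key)
      if (anyNA(idx))
        stop_csdh("csdh_domain_error",
                  "model '%s': score %s outside the risk map domain",
                  spec$name, format(tot[ok][is.na(idx)][1L]))
      p[ok] <- rm$prob[idx]
    } else {
      p[ok] <- approx(rm$key, rm$prob, xout = tot[ok], rule = 2,
                      ties = "ordered")$y
    }
  }
  pc <- ifelse(is.na(p), NA_real_, clip_prob(p))
  data.frame(total = tot, p = pc, lp = ifelse(is.na(pc), NA_real_, logit(pc)))
}

#' @export
print.csdh_model_spec <- function(x, ...) {
  cat(sprintf("<csdh_model_spec> %s\n", x$name))
  cat(sprintf("  outcome: %s\n", x$outcome))
  if (!is.null(x$target_population))
    cat(sprintf("  target population: %s\n", x$target_population))
  cat(sprintf("  predictors: %s\n", paste(model_fields(x), collapse = ", ")))
  cat(sprintf("  risk map: %s (%d rows)\n", x$risk_map$kind,
              length(x$risk_map$key)))
  invisible(x)
}
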