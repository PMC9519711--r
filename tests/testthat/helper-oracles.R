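# Independent reference implementations and fixture builders used across
# the suite.  The oracles deliberately use the naive O(n^2) pairwise
# definitions so they share no code with the package's optimized paths.

# concordance: (concordant + 0.5 * tied) / (event x non-event pairs)
brute_concordance <- function(p, y) {
  ev <- which(y == 1)
  ne <- which(y == 0)
  num <- 0
  for (i in ev) for (j in ne) {
    num <- num + if (p[i] > p[j]) 1 else if (p[i] == p[j]) 0.5 else 0
  }
  num / (length(ev) * length(ne))
}

# model-based concordance over all unordered pairs
brute_mbc <- function(p) {
  n <- length(p)
  num <- 0; den <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    hi <- max(p[i], p[j]); lo <- min(p[i], p[j])
    mass <- hi * (1 - lo) + lo * (1 - hi)
    num <- num + if (p[i] == p[j]) mass / 2 else hi * (1 - lo)
    den <- den + mass
  }
  num / den
}

# the same pairwise definitions written over explicit pair matrices
# (outer products), still O(n^2) and independent of the package's
# prefix-sum / rank shortcuts
brute_concordance_vec <- function(p, y) {
  pe <- p[y == 1]; pn <- p[y == 0]
  (sum(outer(pe, pn, `>`)) + 0.5 * sum(outer(pe, pn, `==`))) /
    (length(pe) * length(pn))
}

brute_mbc_vec <- function(p) {
  hi <- outer(p, p, pmax); lo <- outer(p, p, pmin)
  tie <- outer(p, p, `==`)
  mass <- hi * (1 - lo) + lo * (1 - hi)
  num_m <- ifelse(tie, mass / 2, hi * (1 - lo))
  ut <- upper.tri(mass)
  sum(num_m[ut]) / sum(mass[ut])
}

# a small score-based model over age/gcs/volume with configurable points
toy_score_spec <- function(age_pts = c(0, 1), gcs_pts = c(0, 2, 3),
                           vol_pts = c(0, 1), probs = NULL) {
  scores <- sort(unique(as.vector(
    outer(outer(age_pts, gcs_pts, `+`), vol_pts, `+`))))
  if (is.null(probs)) probs <- expit(-3 + scores)
  model_spec(
    name = "toy", outcome = "mortality_30d",
    predictors = list(
      list(field = "age", kind = "threshold_category", categories = list(
        list(upper = 80, upper_inclusive = FALSE, points = age_pts[1]),
        list(lower = 80, lower_inclusive = TRUE, points = age_pts[2]))),
      list(field = "gcs_category", kind = "named_category", categories = list(
        list(level = "13-15", points = gcs_pts[1]),
        list(level = "5-12", points = gcs_pts[2]),
        list(level = "3-4", points = gcs_pts[3]))),
      list(field = "volume_ml", kind = "threshold_category", categories = list(
        list(upper = 50, upper_inclusive = FALSE, points = vol_pts[1]),
        list(lower = 50, lower_inclusive = TRUE, points = vol_pts[2])))),
    risk_map = list(kind = "score_table",
                    table = Map(function(s, pr)
                      list(score = s, probability = pr), scores, probs)))
}

# model whose risk map is flat: every patient gets probability p0
constant_risk_spec <- function(p0 = 0.5) {
  toy_score_spec(probs = rep(p0, 6))
}

# write a YAML model definition and return its path
write_model_yaml <- function(lines) {
  path <- tempfile(fileext = ".yaml")
  writeLines(lines, path)
  path
}

# tiny deterministic cohort for preprocessing tests
toy_cohort <- function() {
  data.frame(
    patient_id = sprintf("T%02d", 1:6),
    region = c("Amsterdam", "Rotterdam", "North-East", "Rotterdam",
               "Amsterdam", "North-East"),
    age = c(60, 66, 80, 85, 70, 90),
    sex = c("male", "female", "male", "male", "female", "male"),
    gcs_category = c("13-15", "5-12", "13-15", "3-4", "13-15", "5-12"),
    volume_ml = c(40, 120, 200, 80, NA, 55),
    septations = c(FALSE, TRUE, NA, FALSE, TRUE, FALSE),
    laterality = c("unilateral", "unilateral", "unilateral", "bilateral",
                   "unilateral", "unilateral"),
    mortality_30d = c(FALSE, FALSE, TRUE, FALSE, NA, TRUE),
    recurrence_2m = c(FALSE, TRUE, NA, FALSE, FALSE, NA),
    recurrence_3m = c(FALSE, TRUE, NA, TRUE, FALSE, NA),
    stringsAsFactors = FALSE
  )
}
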