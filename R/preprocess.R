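# Preprocessing: derive predictors and outcomes from raw fields, apply
# eligibility and subgroup filters, and build per-model analysis sets.

REGIONS <- c("Amsterdam", "North-East", "Rotterdam")
TREATMENTS <- c("wait_and_see", "surgery", "surgery_plus_dexamethasone",
                "dexamethasone")
OUTCOME_COLS <- c("mortality_30d", "recurrence_2m", "recurrence_3m")

# Fixed-window outcome definitions.  The source registries report
# recurrence at 2 and 3 months; month lengths are conventions, not data,
# so they are package constants: 2 months = 61 days, 3 months = 92 days,
# and the 30-day mortality boundary is inclusive.
DAYS_2M <- 61L
DAYS_3M <- 92L
DAYS_MORTALITY <- 30L

#' Hematoma volume by the ABC/2 formula
#'
#' Estimates hematoma volume as the product of the three orthogonal
#' diameters divided by two: `a * b * c / 2` (diameters in cm give
#' volume in mL).
#'
#' @param a,b,c orthogonal hematoma diameters, cm; must be positive.
#' @return volume in mL.
#' @export
abc2_volume <- function(a, b, c) {
  if (any(!is.finite(a) | a <= 0) || any(!is.finite(b) | b <= 0) ||
      any(!is.finite(c) | c <= 0))
    stop_csdh("csdh_domain_error", "abc2_volume: diameters must be positive")
  a * b * c / 2
}

#' Derive presence of septations from the hematoma type
#'
#' Septation status is deducible from the hematoma-type label only for
#' trabecular/membranous hematomas, which are scored as containing
#' septations; the other named types are scored as not containing
#' septations.  Unknown labels and missing types yield `NA`, never a
#' silent `FALSE`.
#'
#' @param hematoma_type character vector of hematoma-type labels.
#' @return logical vector (septations present), `NA` where unknown.
#' @export
derive_septations <- function(hematoma_type) {
  lv <- norm_level(hematoma_type)
  yes <- c("trabecular", "membranous", "membranous/trabecular")
  no <- c("homogeneous", "mixed", "separated", "laminar", "other")
  out <- rep(NA, length(lv))
  out[lv %in% yes] <- TRUE
  out[lv %in% no] <- FALSE
  out[is.na(hematoma_type)] <- NA
  out
}

#' Derive fixed-window binary outcomes from event day offsets
#'
#' 30-day mortality is death on day 30 or earlier (inclusive boundary).
#' Recurrence is any retreatment event (reoperation or dexamethasone
#' retreatment) within 61 days (2 months) or 92 days (3 months) of
#' diagnosis.
#'
#' @param death_day day of death relative to diagnosis; `NA` when no
#'   death was recorded.
#' @param retreat_days list (one element per patient) of numeric vectors
#'   of retreatment-event day offsets; `numeric(0)` when none.
#' @return data frame with logical columns `mortality_30d`,
#'   `recurrence_2m`, `recurrence_3m`.
#' @export
define_outcomes <- function(death_day, retreat_days) {
  if (!is.list(retreat_days)) retreat_days <- list(retreat_days)
  n <- max(length(death_day), length(retreat_days))
  death_day <- rep_len(death_day, n)
  retreat_days <- rep_len(retreat_days, n)
  if (any(death_day < 0, na.rm = TRUE) ||
      any(vapply(retreat_days, function(d) any(d < 0, na.rm = TRUE), TRUE)))
    stop_csdh("csdh_domain_error",
              "define_outcomes: negative day offsets are invalid")
  rec <- function(days, window)
    vapply(days, function(d) any(d <= window, na.rm = FALSE) %in% TRUE, TRUE)
  data.frame(
    mortality_30d = !is.na(death_day) & death_day <= DAYS_MORTALITY,
    recurrence_2m = rec(retreat_days, DAYS_2M),
    recurrence_3m = rec(retreat_days, DAYS_3M)
  )
}

#' Read a patient cohort from delimited text
#'
#' Comma-separated, header row, one row per patient; empty cells are
#' missing.  Logical columns (`septations`, `hypertension`,
#' `postop_complication`, outcomes) may be coded TRUE/FALSE or 1/0.
#'
#' @param path path to the CSV file.
#' @return a cohort data frame.
#' @export
read_cohort <- function(path) {
  d <- read.csv(path, stringsAsFactors = FALSE, na.strings = c("", "NA"))
  for (col in intersect(c("septations", "hypertension",
                          "postop_complication", OUTCOME_COLS), names(d))) {
    v <- d[[col]]
    if (!is.logical(v)) {
      lv <- norm_level(v)
      out <- rep(NA, length(v))
      out[lv %in% c("true", "1", "yes")] <- TRUE
      out[lv %in% c("false", "0", "no")] <- FALSE
      d[[col]] <- out
    }
  }
  if (!is.null(d$region)) {
    bad <- setdiff(unique(d$region[!is.na(d$region)]), REGIONS)
    if (length(bad))
      stop_csdh("csdh_load_error", "read_cohort: unknown region(s): %s",
                paste(bad, collapse = ", "))
  }
  d
}

#' Write a cohort to delimited text
#'
#' @param cohort cohort data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Restrict a cohort to unilateral hematomas
#'
#' The validated models were all developed for unilateral hematomas, so
#' bilateral records are excluded from every analysis set (they stay in
#' the raw table).  Records with missing laterality are excluded too.
#'
#' @param cohort cohort data frame.
#' @return the unilateral subset, with the number excluded in attribute
#'   `"n_excluded"`.
#' @export
filter_unilateral <- function(cohort) {
  if (is.null(cohort$laterality)) {
    attr(cohort, "n_excluded") <- 0L
    return(cohort)
  }
  keep <- !is.na(cohort$laterality) & cohort$laterality == "unilateral"
  out <- cohort[keep, , drop = FALSE]
  attr(out, "n_excluded") <- sum(!keep)
  out
}

#' Build an analysis set for one model
#'
#' Selects the records a validation analysis operates on: the model's
#' outcome must always be observed (missing outcomes are never imputed);
#' `"complete_case"` additionally requires every model predictor to be
#' observed; an optional subgroup predicate (e.g. `"age > 65"`) and an
#' optional region filter narrow the set further.
#'
#' @param cohort cohort data frame, already restricted to eligible
#'   (unilateral) patients.
#' @param spec a `csdh_model_spec`.
#' @param selection `"complete_case"` or `"imputed"`.
#' @param subgroup optional predicate string evaluated against cohort
#'   columns; rows where it is `NA` are dropped.
#' @param region optional region name.
#' @return the selected data frame, with selection metadata and exclusion
#'   counts in attributes (`"selection"`, `"model"`, `"exclusions"`).
#' @export
select_analysis_set <- function(cohort, spec,
                                selection = c("complete_case", "imputed"),
                                subgroup = NULL, region = NULL) {
  stopifnot(inherits(spec, "csdh_model_spec"))
  selection <- match.arg(selection)
  n0 <- nrow(cohort)
  if (is.null(cohort[[spec$outcome]]))
    stop_csdh("csdh_load_error",
              "cohort lacks outcome column '%s'", spec$outcome)
  excl <- c(outcome_missing = 0L, predictor_missing = 0L,
            subgroup = 0L, region = 0L)

  keep <- !is.na(cohort[[spec$outcome]])
  excl["outcome_missing"] <- sum(!keep)
  d <- cohort[keep, , drop = FALSE]

  if (!is.null(region)) {
    k <- !is.na(d$region) & d$region == region
    excl["region"] <- sum(!k)
    d <- d[k, , drop = FALSE]
  }
  if (!is.null(subgroup)) {
    val <- eval(parse(text = subgroup)[[1L]], envir = d,
                enclos = baseenv())
    k <- !is.na(val) & val
    excl["subgroup"] <- sum(!k)
    d <- d[k, , drop = FALSE]
  }
  if (selection == "complete_case") {
    flds <- model_fields(spec)
    miss <- setdiff(flds, names(d))
    if (length(miss))
      stop_csdh("csdh_load_error", "cohort lacks predictor column(s): %s",
                paste(miss, collapse = ", "))
    k <- complete.cases(d[, flds, drop = FALSE])
    excl["predictor_missing"] <- sum(!k)
    d <- d[k, , drop = FALSE]
  }
  attr(d, "selection") <- selection
  attr(d, "model") <- spec$name
  attr(d, "exclusions") <- excl
  attr(d, "n_input") <- n0
  d
}
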