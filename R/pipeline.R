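# End-to-end orchestration: load cohort and model definitions, build
# analysis sets, run complete-case and imputation analyses (pooled,
# per-region, subgroup), and emit a validation report shaped like the
# standard external-validation results table.

REPORT_COLS <- c("model", "outcome", "analysis", "region", "subgroup",
                 "n", "events", "mean_predicted", "mean_observed",
                 "intercept", "intercept_lower", "intercept_upper",
                 "c_index", "c_lower", "c_upper",
                 "slope", "slope_lower", "slope_upper", "mbc",
                 "status", "reason")

result_row <- function(model, outcome, analysis, region, subgroup, res) {
  data.frame(
    model = model, outcome = outcome, analysis = analysis,
    region = region, subgroup = subgroup,
    n = res$n, events = res$events,
    mean_predicted = res$mean_predicted,
    mean_observed = res$mean_observed,
    intercept = res$intercept$estimate,
    intercept_lower = res$intercept$ci[["lower"]],
    intercept_upper = res$intercept$ci[["upper"]],
    c_index = res$c_index$estimate,
    c_lower = res$c_index$ci[["lower"]],
    c_upper = res$c_index$ci[["upper"]],
    slope = res$slope$estimate,
    slope_lower = res$slope$ci[["lower"]],
    slope_upper = res$slope$ci[["upper"]],
    mbc = res$mbc,
    status = "ok", reason = "",
    stringsAsFactors = FALSE
  )
}

failed_row <- function(model, outcome, analysis, region, subgroup,
                       reason) {
  data.frame(
    model = model, outcome = outcome, analysis = analysis,
    region = region, subgroup = subgroup,
    n = NA_integer_, events = NA_integer_,
    mean_predicted = NA_real_, mean_observed = NA_real_,
    intercept = NA_real_, intercept_lower = NA_real_,
    intercept_upper = NA_real_,
    c_index = NA_real_, c_lower = NA_real_, c_upper = NA_real_,
    slope = NA_real_, slope_lower = NA_real_, slope_upper = NA_real_,
    mbc = NA_real_,
    status = "failed", reason = reason,
    stringsAsFactors = FALSE
  )
}

#' Run a full external-validation analysis
#'
#' For every requested model x analysis x region x subgroup cell:
#' build the analysis set (outcome always observed; complete-case
#' additionally requires all model predictors), evaluate the model, and
#' compute the full set of performance statistics.  Imputation analyses
#' impute the whole eligible cohort once (region and outcomes in every
#' conditional model) and pool across completed datasets with Rubin's
#' rules.  Models with a target population (e.g. age > 65) are validated
#' both in all patients and in that subgroup.  One cell's failure never
#' aborts the run: it is recorded as a failed row with its reason.
#'
#' @param cohort cohort data frame, or path to a cohort CSV.
#' @param models list of `csdh_model_spec` objects and/or paths to model
#'   definition files.
#' @param analyses subset of `c("complete_case", "imputation")`.
#' @param regions `"pooled"`, or `c("pooled", "per_region")` to add one
#'   row per hospital region.
#' @param m,mi_maxit imputation count and chain iterations.
#' @param boot bootstrap replicates for concordance intervals.
#' @param seed global seed; deterministically spawns all sub-seeds.
#' @param min_events minimum events and non-events per cell (smaller
#'   cells are recorded as failed).
#' @param curves also compute decile calibration-curve data per
#'   successful pooled cell?
#' @return object of class `csdh_report`: the results data frame with
#'   provenance attributes (`"seed"`, `"n_cohort"`, `"n_bilateral_excluded"`,
#'   and `"curves"` when requested).
#' @export
run_validation <- function(cohort, models,
                           analyses = c("complete_case", "imputation"),
                           regions = "pooled",
                           m = 10L, mi_maxit = 10L, boot = 2000L,
                           seed = 1L, min_events = 2L, curves = FALSE) {
  if (is.character(cohort)) cohort <- read_cohort(cohort)
  analyses <- match.arg(analyses, c("complete_case", "imputation"),
                        several.ok = TRUE)
  if (!length(models)) stop_csdh("csdh_config_error", "no models supplied")
  specs <- lapply(models, function(mdl) {
    if (inherits(mdl, "csdh_model_spec")) mdl else read_model_spec(mdl)
  })

  eligible <- filter_unilateral(cohort)
  n_bilat <- attr(eligible, "n_excluded")

  region_list <- list(NULL)
  if ("per_region" %in% regions)
    region_list <- c(region_list, as.list(REGIONS))

  stack <- NULL
  if ("imputation" %in% analyses) {
    stack <- impute_chained(eligible,
                            imputation_config(m = m, maxit = mi_maxit,
                                              seed = subseeds(seed, 2L)[1L]))
  }
  boot_seed_pool <- subseeds(subseeds(seed, 2L)[2L],
                             length(specs) * length(region_list) * 4L)
  sidx <- 0L
  rows <- list()
  curve_data <- list()
  for (spec in specs) {
    subgroups <- list(list(label = "all", expr = NULL))
    if (!is.null(spec$target_population))
      subgroups <- c(subgroups,
                     list(list(label = spec$target_population,
                               expr = spec$target_population)))
    for (region in region_list) {
      region_lbl <- if (is.null(region)) "pooled" else region
      for (sg in subgroups) {
        sidx <- sidx + 1L
        cell_seed <- boot_seed_pool[((sidx - 1L) %% length(boot_seed_pool)) + 1L]
        for (analysis in analyses) {
          key <- paste(spec$name, analysis, region_lbl, sg$label,
                       sep = " | ")
          row <- tryCatch({
            if (analysis == "complete_case") {
              d <- select_analysis_set(eligible, spec, "complete_case",
                                       subgroup = sg$expr, region = region)
              if (!nrow(d))
                stop_csdh("csdh_empty_set", "empty analysis set")
              y <- as.integer(d[[spec$outcome]])
              if (sum(y) < min_events || sum(1 - y) < min_events)
                stop_csdh("csdh_empty_set",
                          "fewer than %d events or non-events", min_events)
              pr <- predict_risk(d, spec)
              res <- validate_predictions(pr$p, y, boot = boot,
                                          seed = cell_seed)
              if (curves && region_lbl == "pooled")
                curve_data[[key]] <- calibration_curve(pr$p, y)
              result_row(spec$name, spec$outcome, analysis, region_lbl,
                         sg$label, res)
            } else {
              subset_expr <- sg$expr
              if (!is.null(region)) {
                region_expr <- sprintf('region == "%s"', region)
                subset_expr <- if (is.null(subset_expr)) region_expr
                               else sprintf("(%s) & (%s)", subset_expr,
                                            region_expr)
              }
              res <- pool_validation(stack, spec, subset_expr = subset_expr,
                                     boot = boot, seed = cell_seed)
              if (res$events < min_events ||
                  (res$n - res$events) < min_events)
                stop_csdh("csdh_empty_set",
                          "fewer than %d events or non-events", min_events)
              result_row(spec$name, spec$outcome, analysis, region_lbl,
                         sg$label, res)
            }
          }, error = function(e) {
            failed_row(spec$name, spec$outcome, analysis, region_lbl,
                       sg$label, conditionMessage(e))
          })
          rows[[length(rows) + 1L]] <- row
        }
      }
    }
  }
  report <- do.call(rbind, rows)
  rownames(report) <- NULL
  report <- report[, REPORT_COLS]
  attr(report, "seed") <- seed
  attr(report, "n_cohort") <- nrow(eligible)
  attr(report, "n_bilateral_excluded") <- n_bilat
  if (curves) attr(report, "curves") <- curve_data
  class(report) <- c("csdh_report", "data.frame")
  report
}

#' Render a validation report to files
#'
#' Writes the report as a delimited table (fixed column order mirroring
#' the standard external-validation results layout), optionally a
#' human-readable summary with `estimate [lower, upper]` formatting, and
#' any attached calibration-curve data as delimited files.  Output is
#' byte-identical across renders of the same report.
#'
#' @param report a `csdh_report`.
#' @param dir output directory (created if needed).
#' @param formats subset of `c("delimited", "human")`.
#' @return character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir,
                          formats = c("delimited", "human")) {
  stopifnot(inherits(report, "csdh_report"))
  formats <- match.arg(formats, c("delimited", "human"), several.ok = TRUE)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  if ("delimited" %in% formats) {
    path <- file.path(dir, "validation_report.csv")
    out <- as.data.frame(report)
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(x) round(x, 6))
    write.csv(out, path, row.names = FALSE, na = "")
    written <- c(written, path)
  }
  if ("human" %in% formats) {
    path <- file.path(dir, "validation_report.txt")
    con <- file(path, "w")
    on.exit(close(con), add = TRUE)
    writeLines(sprintf("External validation report (seed %s, n = %s)",
                       attr(report, "seed"), attr(report, "n_cohort")), con)
    for (i in seq_len(nrow(report))) {
      r <- report[i, ]
      writeLines(sprintf("\n%s | %s | %s | %s", r$model, r$analysis,
                         r$region, r$subgroup), con)
      if (r$status != "ok") {
        writeLines(sprintf("  FAILED: %s", r$reason), con)
        next
      }
      writeLines(sprintf("  N/events        %d/%d", r$n, r$events), con)
      writeLines(sprintf("  M pred; M obs   %.1f%%; %.1f%%",
                         100 * r$mean_predicted, 100 * r$mean_observed),
                 con)
      writeLines(sprintf("  Intercept       %.2f [%.2f, %.2f]",
                         r$intercept, r$intercept_lower,
                         r$intercept_upper), con)
      ctxt <- if (is.na(r$c_lower))
        sprintf("  C               %.2f", r$c_index)
      else
        sprintf("  C               %.2f [%.2f, %.2f]", r$c_index,
                r$c_lower, r$c_upper)
      writeLines(ctxt, con)
      writeLines(sprintf("  Slope           %.2f [%.2f, %.2f]",
                         r$slope, r$slope_lower, r$slope_upper), con)
      writeLines(sprintf("  mbc             %.2f", r$mbc), con)
    }
    written <- c(written, path)
  }
  cv <- attr(report, "curves")
  if (!is.null(cv) && length(cv)) {
    for (key in names(cv)) {
      fn <- file.path(dir, paste0(
        "calibration_", gsub("[^A-Za-z0-9]+", "_", key), ".csv"))
      write.csv(cv[[key]], fn, row.names = FALSE)
      written <- c(written, fn)
    }
  }
  invisible(written)
}

#' @export
print.csdh_report <- function(x, ...) {
  cat(sprintf("<csdh_report> %d cells (%d ok, %d failed), cohort n = %s\n",
              nrow(x), sum(x$status == "ok"), sum(x$status != "ok"),
              attr(x, "n_cohort")))
  print.data.frame(
    x[, c("model", "analysis", "region", "subgroup", "n", "events",
          "intercept", "slope", "c_index", "mbc", "status")],
    digits = 3)
  invisible(x)
}

#' Paths to the shipped model definition files
#'
#' The four shipped definitions carry the published categorizations of
#' the Alford SHE score (30-day mortality, age/GCS/volume), the Jack
#' score (2-month recurrence, age/volume/septations), and the two
#' Andersen nomogram models (3-month recurrence; model B preoperative,
#' model A additionally postoperative drainage variables).  Their point
#' values and score-to-risk mappings are synthetic placeholders (the
#' published numeric tables are not redistributed here), which is why the
#' filenames carry the `_synthetic` suffix; replace them with transcribed
#' values for a real validation.
#'
#' @return named character vector of file paths.
#' @export
shipped_model_files <- function() {
  dir <- system.file("extdata", "models", package = "csdhvalid")
  files <- list.files(dir, pattern = "\\.yaml$", full.names = TRUE)
  stats::setNames(files, sub("\\.yaml$", "", basename(files)))
}
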