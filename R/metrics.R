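# Performance metrics for external validation of a binary-outcome risk
# model: calibration-in-the-large and intercept, calibration slope,
# concordance index with bootstrap CI, model-based concordance, and
# calibration-curve data.

check_py <- function(p, y, min_n = 2L) {
  if (length(p) != length(y))
    stop_csdh("csdh_metric_error", "p and y must have equal length")
  if (length(p) < min_n)
    stop_csdh("csdh_metric_error", "need at least %d observations", min_n)
  if (anyNA(p) || anyNA(y))
    stop_csdh("csdh_metric_error", "p and y must be free of missing values")
  if (any(p <= 0 | p >= 1))
    stop_csdh("csdh_metric_error", "probabilities must lie strictly in (0,1)")
  y <- as.integer(y)
  if (!all(y %in% c(0L, 1L)))
    stop_csdh("csdh_metric_error", "y must be binary 0/1")
  y
}

wald_ci <- function(est, se, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  c(lower = est - z * se, upper = est + z * se)
}

glm_fit_checked <- function(formula, data, what) {
  fit <- suppressWarnings(glm(formula, data = data, family = binomial()))
  co <- coef(fit)
  if (!fit$converged || any(!is.finite(co)) || any(abs(co) > 25))
    stop_csdh("csdh_metric_error",
              "%s: logistic fit did not converge (possible separation)", what)
  fit
}

#' Calibration-in-the-large
#'
#' Compares average predicted with average observed risk, and estimates
#' the calibration intercept `a` by maximum likelihood in the offset
#' logistic model `logit Pr(y = 1) = a + lp`, where `lp = logit(p)`
#' enters as a fixed offset (slope constrained to 1).  An intercept above
#' 0 means predictions were on average too low; below 0, too high.
#'
#' @param p predicted probabilities in (0, 1).
#' @param y binary outcomes (0/1 or logical).
#' @param conf confidence level for the Wald interval.
#' @return list with `mean_predicted`, `mean_observed`, `estimate`
#'   (intercept), `se`, `ci`.
#' @export
calibration_in_the_large <- function(p, y, conf = 0.95) {
  y <- check_py(p, y)
  if (sum(y) == 0L || sum(y) == length(y))
    stop_csdh("csdh_metric_error",
              "calibration intercept needs at least one event and one non-event")
  lp <- logit(clip_prob(p))
  fit <- glm_fit_checked(y ~ 1 + offset(lp), data.frame(y = y, lp = lp),
                         "calibration intercept")
  est <- unname(coef(fit)[1L])
  se <- sqrt(vcov(fit)[1L, 1L])
  list(mean_predicted = mean(p), mean_observed = mean(y),
       estimate = est, se = se, ci = wald_ci(est, se, conf))
}

#' Calibration slope
#'
#' Maximum-likelihood fit of `logit Pr(y = 1) = alpha + b * lp`.  A slope
#' below 1 indicates overfitted (too extreme) predictions, above 1
#' underfitted ones.
#'
#' @inheritParams calibration_in_the_large
#' @return list with `estimate` (slope), `se`, `ci`, and the companion
#'   `intercept`.
#' @export
calibration_slope <- function(p, y, conf = 0.95) {
  y <- check_py(p, y)
  if (sum(y) == 0L || sum(y) == length(y))
    stop_csdh("csdh_metric_error",
              "calibration slope needs at least one event and one non-event")
  lp <- logit(clip_prob(p))
  if (var(lp) <= 0)
    stop_csdh("csdh_metric_error",
              "calibration slope undefined: linear predictor is constant")
  fit <- glm_fit_checked(y ~ lp, data.frame(y = y, lp = lp),
                         "calibration slope")
  est <- unname(coef(fit)["lp"])
  se <- sqrt(vcov(fit)["lp", "lp"])
  list(estimate = est, se = se, ci = wald_ci(est, se, conf),
       intercept = unname(coef(fit)[1L]))
}

# Point estimate of C by midranks: ties among predictions receive half
# credit, exactly the (concordant + 0.5 * tied) / (informative pairs)
# convention.  O(n log n).
c_statistic <- function(p, y) {
  n1 <- sum(y == 1L)
  n0 <- sum(y == 0L)
  r <- rank(p, ties.method = "average")
  (sum(r[y == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Concordance index with bootstrap confidence interval
#'
#' Probability that a randomly chosen patient with the outcome received a
#' higher predicted risk than a randomly chosen patient without it; tied
#' predictions are credited 0.5.  The confidence interval is a seeded
#' nonparametric bootstrap (resampling within events and non-events, so
#' every replicate is informative), percentile method.
#'
#' @inheritParams calibration_in_the_large
#' @param ci compute the bootstrap interval? Set `FALSE` for the bare
#'   estimate.
#' @param boot number of bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return list with `estimate`, `ci`, `boot_var` (variance of the
#'   replicates), `boot_var_logit` (variance on the logit scale, used for
#'   pooling across imputations), `n_boot`.
#' @export
concordance_index <- function(p, y, ci = TRUE, boot = 2000, seed = NULL,
                              conf = 0.95) {
  y <- check_py(p, y)
  n1 <- sum(y); n0 <- length(y) - n1
  if (n1 == 0L || n0 == 0L)
    stop_csdh("csdh_metric_error",
              "concordance undefined: no informative event/non-event pairs")
  est <- c_statistic(p, y)
  out <- list(estimate = est, ci = c(lower = NA_real_, upper = NA_real_),
              boot_var = NA_real_, boot_var_logit = NA_real_, n_boot = 0L)
  if (!ci || boot < 2L) return(out)
  ie <- which(y == 1L); ine <- which(y == 0L)
  if (!is.null(seed)) {
    old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(restore_rng(old), add = TRUE)
    set.seed(as.integer(seed))
  }
  cb <- numeric(boot)
  for (b in seq_len(boot)) {
    idx <- c(ie[sample.int(n1, n1, replace = TRUE)],
             ine[sample.int(n0, n0, replace = TRUE)])
    cb[b] <- c_statistic(p[idx], y[idx])
  }
  alpha <- (1 - conf) / 2
  qs <- unname(quantile(cb, c(alpha, 1 - alpha), type = 7))
  out$ci <- c(lower = qs[1L], upper = qs[2L])
  out$boot_var <- var(cb)
  out$boot_var_logit <- var(logit(clip_prob(cb)))
  out$n_boot <- boot
  out
}

#' Model-based concordance
#'
#' The concordance index expected if every predicted probability were the
#' true event probability: over all unordered pairs with `p_i >= p_j` the
#' numerator accumulates `p_i (1 - p_j)` (half the informative mass for
#' exact ties) and the denominator `p_i (1 - p_j) + p_j (1 - p_i)`.  It
#' uses no outcomes, so it reflects case-mix heterogeneity only, not the
#' validity of the model's coefficients.  Computed in O(n log n) via
#' sorted prefix sums; identical to the O(n^2) pairwise sum.
#'
#' @param p predicted probabilities in (0, 1).
#' @return the model-based concordance, a number in \[0, 1\].
#' @export
model_based_concordance <- function(p) {
  if (length(p) < 2L)
    stop_csdh("csdh_metric_error", "model_based_concordance needs n >= 2")
  if (anyNA(p) || any(p <= 0 | p >= 1))
    stop_csdh("csdh_metric_error", "probabilities must lie strictly in (0,1)")
  n <- length(p)
  s1 <- sum(p); s2 <- sum(p^2)
  denom <- (n - 1) * s1 - (s1^2 - s2)
  if (denom <= 0) return(0.5)  # all p identical in the limit
  ps <- sort(p)
  vals <- unique(ps)
  cnt <- tabulate(match(ps, vals))
  cum1mp <- cumsum(cnt * (1 - vals))       # sum of (1-p) up to each value
  num <- 0
  for (k in seq_along(vals)) {
    below <- if (k > 1L) cum1mp[k - 1L] else 0
    num <- num + cnt[k] * vals[k] * below                    # strict pairs
    num <- num + cnt[k] * (cnt[k] - 1) / 2 * vals[k] * (1 - vals[k])  # ties
  }
  num / denom
}

#' Calibration curve data
#'
#' Groups predictions into equal-count risk bins (default deciles) with
#' the mean predicted risk and observed event rate per bin, or evaluates
#' a local-regression smoother of outcome on predicted risk.
#'
#' @inheritParams calibration_in_the_large
#' @param method `"deciles"` (equal-count bins) or `"smoother"` (lowess).
#' @param bins number of equal-count bins for `"deciles"`.
#' @param span smoother span for `"smoother"`.
#' @return data frame with columns `mean_predicted`, `observed`, `n`
#'   (deciles) or `p`, `observed` (smoother); attribute `"method"`, and
#'   `"reduced_bins"` flagged `TRUE` when fewer distinct predictions than
#'   bins forced a fallback.
#' @export
calibration_curve <- function(p, y, method = c("deciles", "smoother"),
                              bins = 10L, span = 0.75) {
  method <- match.arg(method)
  y <- check_py(p, y)
  if (method == "smoother") {
    sm <- lowess(p, y, f = span, iter = 0)
    out <- data.frame(p = sm$x, observed = sm$y)
    attr(out, "method") <- "smoother"
    return(out)
  }
  if (length(p) < 2L * bins && length(p) < 20L)
    stop_csdh("csdh_metric_error",
              "deciles calibration curve needs n >= 20")
  ndist <- length(unique(p))
  reduced <- ndist < bins
  bins_used <- if (reduced) max(1L, ndist) else bins
  ord <- order(p)
  grp <- ceiling(seq_along(ord) / (length(ord) / bins_used))
  if (reduced) {
    # group by distinct value instead, so ties never straddle bins
    grp <- match(p[ord], sort(unique(p)))
  }
  mp <- tapply(p[ord], grp, mean)
  ob <- tapply(y[ord], grp, mean)
  nn <- tapply(y[ord], grp, length)
  out <- data.frame(mean_predicted = as.numeric(mp),
                    observed = as.numeric(ob), n = as.integer(nn))
  attr(out, "method") <- "deciles"
  attr(out, "reduced_bins") <- reduced
  out
}

#' Full validation of one prediction vector
#'
#' Bundles every performance statistic into one result: n, events, mean
#' predicted and observed risk, calibration intercept and slope with 95%
#' Wald intervals, concordance index with bootstrap interval, and the
#' model-based concordance.
#'
#' @inheritParams concordance_index
#' @return object of class `csdh_validation` (a list of the statistics).
#' @export
validate_predictions <- function(p, y, boot = 2000, seed = NULL,
                                 conf = 0.95, ci = TRUE) {
  y <- check_py(p, y)
  citl <- calibration_in_the_large(p, y, conf)
  slope <- calibration_slope(p, y, conf)
  cidx <- concordance_index(p, y, ci = ci, boot = boot, seed = seed,
                            conf = conf)
  structure(list(
    n = length(y), events = sum(y),
    mean_predicted = citl$mean_predicted,
    mean_observed = citl$mean_observed,
    intercept = citl[c("estimate", "se", "ci")],
    slope = slope[c("estimate", "se", "ci")],
    c_index = cidx,
    mbc = model_based_concordance(p),
    conf = conf
  ), class = "csdh_validation")
}

fmt_ci <- function(est, ci) {
  sprintf("%.2f [%.2f, %.2f]", est, ci[["lower"]], ci[["upper"]])
}

#' @export
print.csdh_validation <- function(x, ...) {
  cat(sprintf("<csdh_validation> n = %d, events = %d\n", x$n, x$events))
  cat(sprintf("  mean predicted %.1f%%; mean observed %.1f%%\n",
              100 * x$mean_predicted, 100 * x$mean_observed))
  cat(sprintf("  intercept %s\n", fmt_ci(x$intercept$estimate,
                                         x$intercept$ci)))
  cat(sprintf("  slope     %s\n", fmt_ci(x$slope$estimate, x$slope$ci)))
  if (is.na(x$c_index$ci[["lower"]]))
    cat(sprintf("  C         %.2f\n", x$c_index$estimate))
  else
    cat(sprintf("  C         %s\n", fmt_ci(x$c_index$estimate,
                                           x$c_index$ci)))
  cat(sprintf("  mbc       %.2f\n", x$mbc))
  invisible(x)
}
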