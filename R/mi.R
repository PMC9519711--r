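# Multiple imputation by chained equations and Rubin's-rules pooling.
#
# Conditional models follow the variable's type: predictive mean matching
# (k nearest donors) for continuous variables, Bayesian-draw logistic
# regression for binary ones, multinomial regression for unordered
# categories.  Region enters every conditional model, so a variable that
# was never assessed in one region is imputed from the other regions'
# observations.  Outcome columns are never imputed: they may carry
# missing values throughout and serve only as predictors (with a
# missingness indicator).

#' Imputation configuration
#'
#' @param m number of imputations (default 10).
#' @param maxit iterations per chain (default 10).
#' @param donors predictive-mean-matching donor pool size (default 5).
#' @param outcome_cols columns that must never be imputed; they are still
#'   used as predictors in the conditional models.
#' @param exclude identifier columns excluded from the imputation model.
#' @param seed integer seed; spawns one sub-seed per chain.
#' @return list of class `csdh_mi_config`.
#' @export
imputation_config <- function(m = 10L, maxit = 10L, donors = 5L,
                              outcome_cols = OUTCOME_COLS,
                              exclude = "patient_id", seed = NULL) {
  if (m < 2L) stop_csdh("csdh_mi_error", "imputation needs m >= 2")
  stopifnot(maxit >= 1L, donors >= 1L)
  structure(list(m = as.integer(m), maxit = as.integer(maxit),
                 donors = as.integer(donors), outcome_cols = outcome_cols,
                 exclude = exclude, seed = seed),
            class = "csdh_mi_config")
}

#' Multiple imputation by chained equations
#'
#' Produces `m` completed copies of the cohort from independent chains
#' with distinct sub-seeds.  Every column with missing values (outside
#' `outcome_cols`/`exclude`) is imputed from all other columns, including
#' region and the (never-imputed) outcomes; observed cells are never
#' altered.
#'
#' @param data cohort data frame.
#' @param config a [imputation_config()]; individual fields can also be
#'   overridden through `...` for convenience.
#' @param ... overrides passed to [imputation_config()] when `config` is
#'   missing.
#' @return object of class `csdh_imputed_stack`: list with `completed`
#'   (list of `m` data frames), `where` (logical matrix, `TRUE` =
#'   imputed cell), `config`.
#' @export
impute_chained <- function(data, config = NULL, ...) {
  if (is.null(config)) config <- imputation_config(...)
  stopifnot(inherits(config, "csdh_mi_config"))
  data <- as.data.frame(data)
  model_cols <- setdiff(names(data), config$exclude)
  imp_vars <- model_cols[vapply(data[model_cols], anyNA, TRUE)]
  imp_vars <- setdiff(imp_vars, config$outcome_cols)
  unfillable <- imp_vars[vapply(data[imp_vars],
                                function(v) all(is.na(v)), TRUE)]
  if (length(unfillable))
    stop_csdh("csdh_unimputable",
              "variable(s) with no observed values anywhere: %s",
              paste(unfillable, collapse = ", "))

  where <- vapply(data, is.na, logical(nrow(data)))
  if (nrow(data) == 1L) where <- matrix(where, nrow = 1L,
                                        dimnames = list(NULL, names(data)))
  # missing cells in never-imputed columns stay missing
  for (oc in intersect(config$outcome_cols, names(data)))
    where[, oc] <- FALSE
  for (ex in intersect(config$exclude, names(data)))
    where[, ex] <- FALSE

  seeds <- subseeds(if (is.null(config$seed)) 1L else config$seed, config$m)
  completed <- vector("list", config$m)
  for (j in seq_len(config$m)) {
    completed[[j]] <- run_chain(data, imp_vars, model_cols, config,
                                seeds[j], where)
  }
  structure(list(completed = completed, where = where, config = config,
                 imputed_vars = imp_vars),
            class = "csdh_imputed_stack")
}

run_chain <- function(data, imp_vars, model_cols, config, seed, where) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(seed)
  d <- data
  if (!length(imp_vars)) return(d)
  # initialise missing cells by random draws from the observed margin
  for (v in imp_vars) {
    mis <- where[, v]
    obs <- d[[v]][!is.na(data[[v]])]
    d[[v]][mis] <- sample(obs, sum(mis), replace = TRUE)
  }
  for (it in seq_len(config$maxit)) {
    for (v in imp_vars) {
      mis <- where[, v]
      X <- impute_design(d, setdiff(model_cols, v), config$outcome_cols)
      yv <- data[[v]]          # original, to identify truly observed rows
      obs_rows <- !is.na(yv)
      drawn <- draw_conditional(d[[v]], X, obs_rows, mis, config$donors)
      d[[v]][mis] <- drawn
    }
  }
  d
}

# Design matrix over the given columns of a (currently completed) data
# frame.  Character/factor columns expand to treatment-coded dummies with
# levels taken from the full column; never-imputed columns with residual
# NAs (the outcomes) contribute a zero-filled value plus a missingness
# indicator.  Constant columns are dropped; an intercept is NOT included.
impute_design <- function(d, cols, na_ok_cols) {
  parts <- list()
  for (col in cols) {
    v <- d[[col]]
    if (is.character(v) || is.factor(v)) {
      f <- factor(v)
      lev <- levels(f)
      if (anyNA(f)) {
        f <- addNA(f)
        lev <- levels(f)
      }
      if (length(lev) < 2L) next
      mm <- model.matrix(~ f - 1)
      colnames(mm) <- paste0(col, "::", lev)
      parts[[col]] <- mm[, -1L, drop = FALSE]
    } else {
      x <- as.numeric(v)
      if (anyNA(x)) {
        ind <- as.numeric(is.na(x))
        x[is.na(x)] <- 0
        parts[[col]] <- cbind(setNames(data.frame(x), col),
                              setNames(data.frame(ind),
                                       paste0(col, "::missing")))
      } else {
        parts[[col]] <- setNames(data.frame(x), col)
      }
    }
  }
  X <- as.matrix(do.call(cbind, lapply(parts, as.matrix)))
  keep <- apply(X, 2L, function(z) stats::sd(z) > 0)
  X[, keep, drop = FALSE]
}

draw_conditional <- function(y, X, obs_rows, mis, donors) {
  type <- if (is.logical(y) ||
              (is.numeric(y) && all(y[obs_rows] %in% c(0, 1)))) "binary"
          else if (is.numeric(y)) "continuous"
          else "categorical"
  res <- switch(type,
    continuous = try(draw_pmm(y, X, obs_rows, mis, donors), silent = TRUE),
    binary = try(draw_logistic(y, X, obs_rows, mis), silent = TRUE),
    categorical = try(draw_multinom(y, X, obs_rows, mis), silent = TRUE))
  if (inherits(res, "try-error") || anyNA(res)) {
    # degenerate fit (e.g. separation, rank collapse): marginal draw
    res <- sample(y[obs_rows], sum(mis), replace = TRUE)
  }
  res
}

# drop linearly dependent columns via the QR of the observed design
prune_rank <- function(Xo) {
  q <- qr(cbind(1, Xo))
  keep <- q$pivot[seq_len(q$rank)]
  keep <- setdiff(keep, 1L) - 1L   # column indices of Xo, intercept removed
  keep
}

# Bayesian-draw predictive mean matching (type-1 matching, k donors).
draw_pmm <- function(y, X, obs_rows, mis, donors) {
  keep <- prune_rank(X[obs_rows, , drop = FALSE])
  Xo <- cbind(1, X[obs_rows, keep, drop = FALSE])
  Xm <- cbind(1, X[mis, keep, drop = FALSE])
  yo <- as.numeric(y[obs_rows])
  q <- qr(Xo)
  beta <- qr.coef(q, yo)
  resid <- yo - drop(Xo %*% beta)
  df <- max(length(yo) - q$rank, 1L)
  sigma2_star <- sum(resid^2) / rchisq(1L, df)
  XtX_inv <- chol2inv(chol(crossprod(Xo) + 1e-10 * diag(ncol(Xo))))
  V <- (XtX_inv + t(XtX_inv)) / 2 * sigma2_star
  beta_star <- beta + drop(rnorm(length(beta)) %*% chol(V + 1e-12 * diag(nrow(V))))
  yhat_obs <- drop(Xo %*% beta)
  yhat_mis <- drop(Xm %*% beta_star)
  match_pmm(yo, yhat_obs, yhat_mis, donors)
}

# k-nearest-donor matching on predicted values, via a sorted window.
# Donors are randomly permuted first so that ties in the predicted value
# (common with discrete covariates) are broken at random: every member of
# a tied run is an equally likely donor, not just the few records that a
# stable sort happens to place at the run's boundary.
match_pmm <- function(yo, yhat_obs, yhat_mis, donors) {
  perm <- sample.int(length(yo))
  yo <- yo[perm]
  yhat_obs <- yhat_obs[perm]
  ord <- order(yhat_obs)
  ys <- yhat_obs[ord]
  n <- length(ys)
  k <- min(donors, n)
  pos <- findInterval(yhat_mis, ys)
  out <- numeric(length(yhat_mis))
  for (i in seq_along(yhat_mis)) {
    lo <- max(1L, pos[i] - k)
    hi <- min(n, pos[i] + k)
    cand <- lo:hi
    dd <- abs(ys[cand] - yhat_mis[i])
    pick <- cand[order(dd)[seq_len(min(k, length(cand)))]]
    out[i] <- yo[ord[pick[sample.int(length(pick), 1L)]]]
  }
  out
}

draw_logistic <- function(y, X, obs_rows, mis) {
  keep <- prune_rank(X[obs_rows, , drop = FALSE])
  Xo <- cbind(1, X[obs_rows, keep, drop = FALSE])
  Xm <- cbind(1, X[mis, keep, drop = FALSE])
  yo <- as.numeric(y[obs_rows])
  fit <- suppressWarnings(
    stats::glm.fit(Xo, yo, family = binomial(),
                   control = list(maxit = 50)))
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 25))
    stop("unstable logistic conditional")
  W <- fit$weights
  V <- chol2inv(chol(crossprod(Xo * sqrt(W)) + 1e-10 * diag(ncol(Xo))))
  beta_star <- MASS::mvrnorm(1L, beta, V)
  pm <- expit(drop(Xm %*% beta_star))
  drawn <- rbinom(length(pm), 1L, pm)
  if (is.logical(y)) as.logical(drawn) else drawn
}

draw_multinom <- function(y, X, obs_rows, mis) {
  keep <- prune_rank(X[obs_rows, , drop = FALSE])
  df_fit <- data.frame(.y = factor(y[obs_rows]),
                       X[obs_rows, keep, drop = FALSE])
  df_mis <- data.frame(X[mis, keep, drop = FALSE])
  names(df_mis) <- names(df_fit)[-1L]
  fit <- nnet::multinom(.y ~ ., data = df_fit, trace = FALSE, maxit = 200)
  pr <- predict(fit, newdata = df_mis, type = "probs")
  lev <- levels(df_fit$.y)
  if (is.null(dim(pr))) {
    pr <- if (length(lev) == 2L) cbind(1 - pr, pr) else matrix(pr, nrow = 1L)
  }
  idx <- apply(pr, 1L, function(prob)
    sample.int(length(prob), 1L, prob = prob))
  out <- lev[idx]
  if (is.factor(y)) factor(out, levels = levels(y)) else out
}

#' Extract one completed dataset
#'
#' @param stack a `csdh_imputed_stack`.
#' @param j imputation index in `1..m`.
#' @return the j-th completed data frame.
#' @export
complete_data <- function(stack, j = 1L) {
  stopifnot(inherits(stack, "csdh_imputed_stack"),
            j >= 1L, j <= stack$config$m)
  stack$completed[[j]]
}

#' @export
print.csdh_imputed_stack <- function(x, ...) {
  cat(sprintf("<csdh_imputed_stack> m = %d, n = %d\n",
              x$config$m, nrow(x$completed[[1L]])))
  cat(sprintf("  imputed variables: %s\n",
              if (length(x$imputed_vars))
                paste(x$imputed_vars, collapse = ", ") else "(none)"))
  invisible(x)
}

#' Pool estimates across imputations with Rubin's rules
#'
#' Combines per-imputation estimates and variances: pooled estimate is
#' the mean, within-imputation variance `W` the mean variance, between
#' variance `B` the sample variance of the estimates, total variance
#' `T = W + (1 + 1/m) B`.  The confidence interval uses a t reference
#' with Barnard-Rubin degrees of freedom when the complete-data degrees
#' of freedom `dfcom` are finite, the classical large-sample Rubin
#' degrees of freedom otherwise.
#'
#' @param estimates numeric vector of per-imputation estimates.
#' @param variances numeric vector of per-imputation (squared-SE)
#'   variances.
#' @param dfcom complete-data degrees of freedom (`Inf` for the
#'   large-sample formula).
#' @param conf confidence level.
#' @return list of class `csdh_pooled`: `estimate`, `W`, `B`, `Total`,
#'   `se`, `df`, `ci`, `m`.
#' @export
rubin_pool <- function(estimates, variances, dfcom = Inf, conf = 0.95) {
  m <- length(estimates)
  if (m < 2L || length(variances) != m)
    stop_csdh("csdh_mi_error",
              "rubin_pool needs >= 2 estimates with matching variances")
  if (anyNA(estimates) || anyNA(variances) || any(variances < 0))
    stop_csdh("csdh_mi_error",
              "rubin_pool: estimates/variances must be non-missing, variances >= 0")
  est <- mean(estimates)
  W <- mean(variances)
  B <- var(estimates)
  Total <- W + (1 + 1 / m) * B
  if (B <= 0 || Total <= 0) {
    df <- Inf
  } else {
    lambda <- (1 + 1 / m) * B / Total
    df_old <- (m - 1) / lambda^2
    if (is.finite(dfcom)) {
      nu_obs <- (dfcom + 1) / (dfcom + 3) * dfcom * (1 - lambda)
      df <- df_old * nu_obs / (df_old + nu_obs)
    } else df <- df_old
  }
  se <- sqrt(Total)
  tq <- if (is.finite(df)) qt(1 - (1 - conf) / 2, df)
        else qnorm(1 - (1 - conf) / 2)
  structure(list(estimate = est, W = W, B = B, Total = Total, se = se,
                 df = df, ci = c(lower = est - tq * se,
                                 upper = est + tq * se), m = m),
            class = "csdh_pooled")
}

#' Validate predictions across an imputed stack
#'
#' Computes the full validation result on every completed dataset and
#' pools: intercept and slope on their natural logistic-coefficient scale
#' with Wald variances; the concordance index on the log-odds scale
#' (bootstrap variance mapped by the delta method) with back-transform;
#' the model-based concordance and mean predicted risk as plain averages
#' (they vary only through imputed predictor values).
#'
#' @param stack a `csdh_imputed_stack`.
#' @param predict_fun function mapping a completed data frame to
#'   predicted probabilities (e.g. built from [predict_risk()]).
#' @param outcome outcome column name; rows with missing outcome are
#'   dropped (missing outcomes are never imputed).
#' @param subset_expr optional predicate string evaluated on each
#'   completed dataset (subgroup/region filters).
#' @param boot,seed,conf bootstrap settings for the per-imputation
#'   concordance.
#' @return object of class `csdh_validation_pooled`.
#' @export
validate_imputed <- function(stack, predict_fun, outcome,
                             subset_expr = NULL, boot = 2000, seed = NULL,
                             conf = 0.95) {
  stopifnot(inherits(stack, "csdh_imputed_stack"))
  m <- stack$config$m
  seeds <- subseeds(if (is.null(seed)) 1L else seed, m)
  per <- vector("list", m)
  for (j in seq_len(m)) {
    d <- stack$completed[[j]]
    keep <- !is.na(d[[outcome]])
    if (!is.null(subset_expr)) {
      val <- eval(parse(text = subset_expr)[[1L]], envir = d,
                  enclos = baseenv())
      keep <- keep & !is.na(val) & val
    }
    d <- d[keep, , drop = FALSE]
    if (!nrow(d))
      stop_csdh("csdh_empty_set", "imputation %d: empty analysis set", j)
    p <- predict_fun(d)
    res <- tryCatch(
      validate_predictions(p, d[[outcome]], boot = boot, seed = seeds[j],
                           conf = conf),
      csdh_error = function(e)
        stop_csdh("csdh_mi_error", "imputation %d: %s", j, conditionMessage(e)))
    per[[j]] <- res
  }
  n <- per[[1L]]$n
  g <- function(f) vapply(per, f, 0)
  a <- rubin_pool(g(function(r) r$intercept$estimate),
                  g(function(r) r$intercept$se)^2, dfcom = n - 1, conf = conf)
  b <- rubin_pool(g(function(r) r$slope$estimate),
                  g(function(r) r$slope$se)^2, dfcom = n - 2, conf = conf)
  cc <- g(function(r) r$c_index$estimate)
  cv <- g(function(r) r$c_index$boot_var_logit)
  if (any(is.na(cv))) {
    cl <- list(estimate = mean(cc), ci = c(lower = NA_real_,
                                           upper = NA_real_))
  } else {
    pooled_logit <- rubin_pool(logit(clip_prob(cc)), cv, dfcom = n - 1,
                               conf = conf)
    cl <- list(estimate = expit(pooled_logit$estimate),
               ci = c(lower = expit(pooled_logit$ci[["lower"]]),
                      upper = expit(pooled_logit$ci[["upper"]])))
  }
  structure(list(
    n = n, events = per[[1L]]$events, m = m,
    mean_predicted = mean(g(function(r) r$mean_predicted)),
    mean_observed = per[[1L]]$mean_observed,
    intercept = list(estimate = a$estimate, se = a$se, ci = a$ci,
                     pooled = a),
    slope = list(estimate = b$estimate, se = b$se, ci = b$ci, pooled = b),
    c_index = cl,
    mbc = mean(g(function(r) r$mbc)),
    per_imputation = per, conf = conf
  ), class = c("csdh_validation_pooled", "csdh_validation"))
}

#' Pooled validation of a published model on an imputed stack
#'
#' Convenience wrapper around [validate_imputed()] that derives the
#' prediction function and outcome from a `csdh_model_spec`.
#'
#' @param stack a `csdh_imputed_stack`.
#' @param spec a `csdh_model_spec`.
#' @inheritParams validate_imputed
#' @return object of class `csdh_validation_pooled`.
#' @export
pool_validation <- function(stack, spec, subset_expr = NULL, boot = 2000,
                            seed = NULL, conf = 0.95) {
  stopifnot(inherits(spec, "csdh_model_spec"))
  validate_imputed(stack,
                   predict_fun = function(d) predict_risk(d, spec)$p,
                   outcome = spec$outcome, subset_expr = subset_expr,
                   boot = boot, seed = seed, conf = conf)
}
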