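# Shared numerical helpers.

#' Clip probabilities away from 0 and 1
#'
#' Probabilities are clipped into `[eps, 1 - eps]` before taking logits so
#' that linear predictors stay finite even for degenerate risk maps.
#'
#' @param p numeric vector of probabilities.
#' @param eps clipping bound, default `1e-6`.
#' @return clipped numeric vector.
#' @export
clip_prob <- function(p, eps = 1e-6) {
  stopifnot(is.numeric(p), eps > 0, eps < 0.5)
  pmin(pmax(p, eps), 1 - eps)
}

#' Logit and inverse logit
#'
#' @param p probabilities in (0, 1).
#' @return `logit()` returns `log(p/(1-p))`; `expit()` its inverse.
#' @export
logit <- function(p) log(p / (1 - p))

#' @rdname logit
#' @param x real-valued linear predictor.
#' @export
expit <- function(x) 1 / (1 + exp(-x))

# Deterministically spawn n sub-seeds from one global seed, so that one
# number reproduces every stochastic component (imputation chains,
# bootstrap, simulation).  Kept below .Machine$integer.max.
subseeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, n >= 1)
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Truncated normal sampling by inverse-CDF; exact, vector-safe, and cheap
# for the mild truncations used by the cohort generator.
rtruncnorm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  stopifnot(sd > 0, lower < upper)
  plo <- stats::pnorm(lower, mean, sd)
  phi <- stats::pnorm(upper, mean, sd)
  u <- runif(n, plo, phi)
  stats::qnorm(u, mean, sd)
}

# Mean and sd of N(mu, sigma) truncated to [lower, upper].
truncnorm_moments <- function(mu, sigma, lower, upper) {
  a <- (lower - mu) / sigma
  b <- (upper - mu) / sigma
  pa <- stats::dnorm(a); pb <- stats::dnorm(b)
  apa <- if (is.finite(a)) a * pa else 0
  bpb <- if (is.finite(b)) b * pb else 0
  Z <- stats::pnorm(b) - stats::pnorm(a)
  d <- (pa - pb) / Z
  m <- mu + sigma * d
  v <- sigma^2 * (1 + (apa - bpb) / Z - d^2)
  c(mean = m, sd = sqrt(v))
}

# Underlying normal parameters whose TRUNCATED distribution has the given
# mean and sd: the configured targets are observed (truncated-scale)
# marginals, so sampling must match them after truncation.
truncnorm_params <- function(target_mean, target_sd, lower, upper) {
  obj <- function(par) {
    mom <- truncnorm_moments(par[1L], exp(par[2L]), lower, upper)
    (mom[["mean"]] - target_mean)^2 + (mom[["sd"]] - target_sd)^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 2000))
  c(mean = fit$par[1L], sd = exp(fit$par[2L]))
}

# Condition helpers: classed errors so callers can branch on failure kind.
csdh_error <- function(class, message, ...) {
  structure(
    class = c(class, "csdh_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  )
}

stop_csdh <- function(class, fmt, ...) {
  stop(csdh_error(class, sprintf(fmt, ...)))
}
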