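#' Estimate a log hazard ratio from IPD with the Cox model
#'
#' Fits a Cox proportional hazards model with a single arm indicator to an
#' IPD table (columns `arm`, `time_months`, `event`) and returns the log
#' hazard ratio of `comp_arm` relative to `ref_arm` with its standard error.
#' Ties are handled by the Breslow approximation by default (adequate for
#' reconstructed IPD); Efron is available behind the `ties` flag.
#'
#' @param ipd IPD tibble (see [read_ipd_table()] for the schema).
#' @param ref_arm,comp_arm Arm codes present in `ipd$arm`.
#' @param ties `"breslow"` (default) or `"efron"`.
#' @return A tibble with columns `loghr`, `se`, `n_events`.
#' @examples
#' ipd <- simulate_ipd(200, shape = 1, rate = 0.05, hr = 0.7, seed = 1)
#' fit_cox_loghr(ipd, "ref", "comp")
#' @export
fit_cox_loghr <- function(ipd, ref_arm, comp_arm,
                          ties = c("breslow", "efron")) {
  ties <- match.arg(ties)
  ipd <- validate_ipd(ipd)
  dat <- ipd[ipd$arm %in% c(ref_arm, comp_arm), ]
  if (!any(dat$arm == ref_arm) || !any(dat$arm == comp_arm)) {
    abort("Both `ref_arm` and `comp_arm` must be present in the IPD.")
  }
  if (sum(dat$event) < 1) {
    abort("Cannot estimate a hazard ratio: no events in the pooled data.")
  }
  dat$z <- as.integer(dat$arm == comp_arm)
  fit <- survival::coxph(
    survival::Surv(time_months, event) ~ z, data = dat, ties = ties
  )
  if (!is.finite(stats::coef(fit)) || !is.finite(sqrt(fit$var[1, 1]))) {
    abort("Cox fit did not converge to a finite estimate.")
  }
  tibble(
    loghr = unname(stats::coef(fit)),
    se = sqrt(fit$var[1, 1]),
    n_events = sum(dat$event)
  )
}

#' Weibull maximum likelihood fit for right-censored survival data
#'
#' Maximizes the right-censored Weibull likelihood in the
#' `S(t) = exp(-rate * t^shape)` convention used throughout the transition
#' -probability machinery, by Newton-type optimization on
#' `(log(rate), log(shape))`. The asymptotic covariance on that log scale is
#' returned for probabilistic sensitivity analysis sampling.
#'
#' @param ipd IPD tibble.
#' @param arm Optional arm code; if supplied, only that arm is fitted.
#' @return An object of class `weibull_fit`: a list with `shape`, `rate`,
#'   `log_par` (named vector `log_rate`, `log_shape`), `vcov_log` (2x2),
#'   `loglik`, `n`, `n_events`.
#' @examples
#' ipd <- simulate_ipd(500, shape = 1.2, rate = 0.02, seed = 1)
#' fit_weibull_mle(ipd, arm = "ref")
#' @export
fit_weibull_mle <- function(ipd, arm = NULL) {
  ipd <- validate_ipd(ipd)
  if (!is.null(arm)) ipd <- ipd[ipd$arm == arm, ]
  t <- ipd$time_months
  d <- ipd$event
  if (sum(d) < 2) {
    abort("Weibull estimation needs at least 2 events (all-censored or near-degenerate arm).")
  }
  if (any(t[d == 1] <= 0)) {
    abort("Event times must be strictly positive for the Weibull model.")
  }
  t <- pmax(t, .Machine$double.eps)
  lt <- log(t)
  negll <- function(p) {
    lam <- exp(p[1]); gam <- exp(p[2])
    -(sum(d * (log(lam) + log(gam) + (gam - 1) * lt)) -
        lam * sum(t^gam))
  }
  negll_grad <- function(p) {
    lam <- exp(p[1]); gam <- exp(p[2])
    tg <- t^gam
    c(-(sum(d) - lam * sum(tg)),
      -(sum(d) + gam * (sum(d * lt) - lam * sum(tg * lt))))
  }
  # moment-style start: exponential rate, unit shape
  p0 <- c(log(sum(d) / sum(t)), 0)
  opt <- optim(p0, negll, gr = negll_grad, method = "BFGS",
               hessian = TRUE,
               control = list(maxit = 500, reltol = 1e-14))
  if (opt$convergence != 0) {
    abort(paste0("Weibull MLE did not converge (optim code ",
                 opt$convergence, ")."))
  }
  vcov_log <- tryCatch(solve(opt$hessian), error = function(e) {
    abort("Weibull MLE information matrix is singular.")
  })
  dimnames(vcov_log) <- list(c("log_rate", "log_shape"),
                             c("log_rate", "log_shape"))
  structure(
    list(
      shape = exp(opt$par[2]),
      rate = exp(opt$par[1]),
      log_par = c(log_rate = opt$par[1], log_shape = opt$par[2]),
      vcov_log = vcov_log,
      loglik = -opt$value,
      n = length(t),
      n_events = sum(d)
    ),
    class = "weibull_fit"
  )
}

#' @export
print.weibull_fit <- function(x, ...) {
  cat("Weibull fit, S(t) = exp(-rate * t^shape)\n")
  cat(sprintf("  shape = %.4f, rate = %.6f  (n = %d, events = %d)\n",
              x$shape, x$rate, x$n, x$n_events))
  cat(sprintf("  mean survival %.2f months\n", weibull_mean(x$shape, x$rate)))
  invisible(x)
}

#' Mean survival time of a Weibull distribution
#'
#' Under `S(t) = exp(-rate * t^shape)` the mean is
#' `gamma(1 + 1/shape) * rate^(-1/shape)`.
#'
#' @param shape,rate Positive Weibull parameters (vectorised).
#' @return Mean survival time in the time unit of `rate` (months here).
#' @examples
#' weibull_mean(1, 0.05) # exponential mean 1/rate = 20
#' @export
weibull_mean <- function(shape, rate) {
  if (any(shape <= 0) || any(rate <= 0)) {
    abort("`shape` and `rate` must be positive.")
  }
  gamma(1 + 1 / shape) * rate^(-1 / shape)
}

#' @export
tidy.weibull_fit <- function(x, ...) {
  se <- sqrt(diag(x$vcov_log))
  tibble(
    term = c("rate", "shape"),
    estimate = c(x$rate, x$shape),
    log_estimate = unname(x$log_par),
    log_se = unname(se)
  )
}

#' @export
glance.weibull_fit <- function(x, ...) {
  tibble(n = x$n, n_events = x$n_events, logLik = x$loglik,
         mean_survival = weibull_mean(x$shape, x$rate))
}
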