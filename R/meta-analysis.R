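#' Bayesian pairwise meta-analysis of log hazard ratios
#'
#' `fit_ma_common()` pools estimates under a common-effect normal model with
#' a vague normal prior (mean 0, variance 10^3) on the pooled effect; its
#' posterior mean agrees with the closed-form inverse-variance estimate up
#' to Monte Carlo error. `fit_ma_random()` fits the normal-normal
#' hierarchical model with a half-normal prior on the between-study SD and
#' additionally returns the heterogeneity SD `tau` and the predictive
#' distribution `pred` for the effect in a new study.
#'
#' @param data A data frame with columns `y` (estimate, e.g. log HR) and
#'   `se` (standard error > 0).
#' @param mcmc An [mcmc_control()].
#' @param prior_mean_var Variance of the normal prior on the pooled effect.
#' @param prior_tau_var Variance of the half-normal prior on `tau`
#'   (random-effects model).
#' @return An object of class `ma_fit` with elements `draws` (tibble of
#'   posterior draws), `summary` (log and HR scale), `diagnostics`,
#'   `variant`, and `data`.
#' @examples
#' \donttest{
#' est <- tibble::tibble(y = c(0.2, 0.4), se = c(0.1, 0.2))
#' fit <- fit_ma_common(est, mcmc_control(4000, 1000, 2, seed = 1))
#' tidy(fit)
#' }
#' @export
fit_ma_common <- function(data, mcmc = mcmc_control(),
                          prior_mean_var = 1e3) {
  data <- check_ma_data(data, min_n = 1)
  model <- "
  model {
    for (i in 1:N) {
      y[i] ~ dnorm(theta, 1 / (se[i] * se[i]))
    }
    theta ~ dnorm(0, prior_prec)
  }"
  res <- run_jags(
    model,
    data = list(y = data$y, se = data$se, N = nrow(data),
                prior_prec = 1 / prior_mean_var),
    params = "theta", mcmc = mcmc,
    inits = function(k) list(theta = sum(data$y / data$se^2) /
                               sum(1 / data$se^2))
  )
  new_ma_fit(res, "common", data)
}

#' @rdname fit_ma_common
#' @export
fit_ma_random <- function(data, mcmc = mcmc_control(),
                          prior_mean_var = 1e3, prior_tau_var = 1e3) {
  data <- check_ma_data(data, min_n = 2)
  model <- "
  model {
    for (i in 1:N) {
      y[i] ~ dnorm(theta[i], 1 / (se[i] * se[i]))
      theta[i] ~ dnorm(mu, prec_tau)
    }
    mu ~ dnorm(0, prior_prec)
    tau ~ dnorm(0, prior_prec_tau) T(0,)
    prec_tau <- 1 / (tau * tau)
    pred ~ dnorm(mu, prec_tau)
  }"
  res <- run_jags(
    model,
    data = list(y = data$y, se = data$se, N = nrow(data),
                prior_prec = 1 / prior_mean_var,
                prior_prec_tau = 1 / prior_tau_var),
    params = c("mu", "tau", "pred"), mcmc = mcmc,
    inits = function(k) list(mu = mean(data$y), tau = max(sd(data$y), 0.05))
  )
  new_ma_fit(res, "random", data)
}

check_ma_data <- function(data, min_n) {
  data <- as_tibble(data)
  if (!all(c("y", "se") %in% names(data))) {
    abort("Meta-analysis data needs columns `y` and `se`.")
  }
  data <- data[stats::complete.cases(data[, c("y", "se")]), ]
  if (nrow(data) < min_n) {
    abort(paste0("At least ", min_n, " estimate(s) required."))
  }
  if (any(data$se <= 0)) abort("All standard errors must be positive.")
  data
}

new_ma_fit <- function(res, variant, data) {
  pooled <- if (variant == "common") "theta" else "mu"
  smry <- summarise_draws(res$draws, c(pooled, "tau", "pred"))
  smry <- add_hr_scale(smry)
  converged <- check_convergence(res$diagnostics,
                                 paste0(variant, "-effect meta-analysis"))
  structure(
    list(draws = res$draws, summary = smry, diagnostics = res$diagnostics,
         variant = variant, data = data, pooled_param = pooled,
         converged = converged),
    class = "ma_fit"
  )
}

#' Posterior draws of the pooled effect of a meta-analysis fit
#'
#' @param fit An `ma_fit`.
#' @return Numeric vector of pooled-effect draws on the log HR scale.
#' @export
pooled_draws <- function(fit) {
  stopifnot(inherits(fit, "ma_fit"))
  fit$draws[[fit$pooled_param]]
}

#' @export
print.ma_fit <- function(x, ...) {
  cat(sprintf("Bayesian %s-effect meta-analysis (%d studies)\n",
              x$variant, nrow(x$data)))
  pl <- x$summary[x$summary$param == x$pooled_param, ]
  cat(sprintf("  pooled HR %.3f (95%% CrI %.3f-%.3f)\n",
              pl$hr, pl$hr_q2.5, pl$hr_q97.5))
  if (x$variant == "random") {
    tau <- x$summary[x$summary$param == "tau", ]
    cat(sprintf("  between-study SD tau: median %.3f (95%% CrI %.3f-%.3f)\n",
                tau$median, tau$q2.5, tau$q97.5))
  }
  invisible(x)
}

#' @export
tidy.ma_fit <- function(x, ...) x$summary

#' @export
glance.ma_fit <- function(x, ...) {
  tibble(
    variant = x$variant, n_studies = nrow(x$data),
    n_draws = nrow(x$draws),
    min_ess = min(x$diagnostics$ess),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    converged = x$converged
  )
}
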