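#' Priors for the bivariate random-effects meta-analysis
#'
#' Vague defaults follow the evidence-synthesis convention: normal priors
#' with variance 10^3 on location parameters, half-normal priors with
#' variance 10^3 on the between-study SDs, and Uniform(-1, 1) priors on the
#' between- and within-study correlations. The within-study correlations
#' are only weakly identified from aggregate data; `rho_w_fixed` pins them
#' to an externally informed value instead of sampling them.
#'
#' The hyperpriors of the exchangeable log-variance model used to predict
#' the standard error of an unreported estimate (vague normal on the mean,
#' Uniform(0, `logvar_sd_upper`) on the SD of study log-variances) are also
#' set here.
#'
#' @param mean_var Variance of the normal priors on `eta_os` and `lambda0`.
#' @param tau_var Variance of the half-normal priors on `tau_os`, `tau_pfs`.
#' @param rho_b_bounds,rho_w_bounds Support of the uniform correlation
#'   priors, within `[-1, 1]`.
#' @param rho_w_fixed Optional scalar or per-study vector of within-study
#'   correlations to treat as known.
#' @param logvar_sd_upper Upper bound of the uniform hyperprior on the SD of
#'   the exchangeable study log-variances.
#' @return A list of class `brma_priors`.
#' @export
brma_priors <- function(mean_var = 1e3, tau_var = 1e3,
                        rho_b_bounds = c(-1, 1), rho_w_bounds = c(-1, 1),
                        rho_w_fixed = NULL, logvar_sd_upper = 2) {
  stopifnot(mean_var > 0, tau_var > 0,
            all(abs(rho_b_bounds) <= 1), rho_b_bounds[1] < rho_b_bounds[2],
            all(abs(rho_w_bounds) <= 1), rho_w_bounds[1] < rho_w_bounds[2],
            logvar_sd_upper > 0)
  if (!is.null(rho_w_fixed)) stopifnot(all(abs(rho_w_fixed) < 1))
  structure(
    list(mean_var = mean_var, tau_var = tau_var,
         rho_b_bounds = rho_b_bounds, rho_w_bounds = rho_w_bounds,
         rho_w_fixed = rho_w_fixed, logvar_sd_upper = logvar_sd_upper),
    class = "brma_priors"
  )
}

# Product-normal BRMA. Within-study level: the observed (OS, PFS) log HRs
# are bivariate normal around the true study effects with known-given-data
# SEs and correlation rho_w[i], written as a marginal for OS and a
# conditional regression for PFS. Between-study level: mu_os ~ N(eta_os,
# tau_os^2) and mu_pfs | mu_os ~ N(lambda0 + lambda1 (mu_os - eta_os),
# psi^2) with lambda1 = rho_b tau_pfs / tau_os and
# psi^2 = tau_pfs^2 (1 - rho_b^2). Study log-variances are exchangeable
# normal per outcome, so an unreported estimate gets both its true-effect
# prediction and a predicted within-study SE; its observed-scale value is
# the node JAGS samples for the missing y. A 1e-10 floor keeps the
# conditional precision finite when tau_pfs or 1-rho_b^2 degenerate.
.brma_model <- "
model {
  for (i in 1:N) {
    logv_os[i] ~ dnorm(m_v_os, prec_v_os)
    logv_pfs[i] ~ dnorm(m_v_pfs, prec_v_pfs)
    s_os[i] <- sqrt(exp(logv_os[i]))
    s_pfs[i] <- sqrt(exp(logv_pfs[i]))
    y_os[i] ~ dnorm(mu_os[i], 1 / exp(logv_os[i]))
    cmean[i] <- mu_pfs[i] +
      rho_w[i] * s_pfs[i] / s_os[i] * (y_os[i] - mu_os[i])
    cvar[i] <- exp(logv_pfs[i]) * (1 - rho_w[i] * rho_w[i]) + 1.0E-10
    y_pfs[i] ~ dnorm(cmean[i], 1 / cvar[i])
    mu_os[i] ~ dnorm(eta_os, prec_os)
    eta_pfs[i] <- lambda0 + lambda1 * (mu_os[i] - eta_os)
    mu_pfs[i] ~ dnorm(eta_pfs[i], prec_cond)
  }
  eta_os ~ dnorm(0, prior_prec_mean)
  lambda0 ~ dnorm(0, prior_prec_mean)
  tau_os ~ dnorm(0, prior_prec_tau) T(0,)
  tau_pfs ~ dnorm(0, prior_prec_tau) T(0,)
  rho_b ~ dunif(rho_b_lo, rho_b_hi)
  lambda1 <- rho_b * tau_pfs / tau_os
  prec_os <- 1 / (tau_os * tau_os + 1.0E-10)
  psq_pfs <- tau_pfs * tau_pfs * (1 - rho_b * rho_b)
  prec_cond <- 1 / (psq_pfs + 1.0E-10)
  m_v_os ~ dnorm(0, 0.001)
  m_v_pfs ~ dnorm(0, 0.001)
  sd_v_os ~ dunif(0, logvar_sd_upper)
  sd_v_pfs ~ dunif(0, logvar_sd_upper)
  prec_v_os <- 1 / (sd_v_os * sd_v_os + 1.0E-10)
  prec_v_pfs <- 1 / (sd_v_pfs * sd_v_pfs + 1.0E-10)
"

#' Bivariate random-effects meta-analysis with missing-outcome prediction
#'
#' Jointly models study-level log hazard ratios on overall survival and
#' progression-free survival, correlated both within studies (sampling
#' correlation `rho_w`) and between studies (heterogeneity correlation
#' `rho_b`), using the product-normal factorization of the between-study
#' bivariate normal. Studies whose PFS (or OS) estimate is missing
#' contribute their reported outcome, and the missing observed effect is
#' predicted directly from the MCMC simulation: its true effect comes from
#' the conditional between-study regression, and its within-study standard
#' error from an exchangeable model on the observed study log-variances.
#'
#' @param studies A [study_table()] (missing outcomes as `NA`).
#' @param priors A [brma_priors()].
#' @param mcmc An [mcmc_control()]; defaults to 30,000 iterations with
#'   15,000 burn-in on 2 chains.
#' @param force Proceed (with a warning) when fewer than 2 studies report
#'   both outcomes, leaving the correlation essentially unidentified.
#' @return An object of class `brma_fit` with elements `draws` (all
#'   monitored nodes), `summary`, `predictions` (one row per missing entry,
#'   log and HR scale), `pred_draws` (per-draw predicted observed effects),
#'   `diagnostics`, `converged`, and `studies`.
#' @examples
#' \donttest{
#' fx <- hta_fixture()
#' fit <- fit_brma(fx$studies, mcmc = mcmc_control(6000, 2000, 2, seed = 1))
#' fit$predictions
#' }
#' @export
fit_brma <- function(studies, priors = brma_priors(),
                     mcmc = mcmc_control(), force = FALSE) {
  studies <- validate_study_table(studies)
  stopifnot(inherits(priors, "brma_priors"))
  n <- nrow(studies)
  if (n < 2) abort("BRMA needs at least 2 studies.")
  if (all(is.na(studies$loghr_pfs))) {
    abort("All PFS estimates are missing: the PFS level of the model is unidentified.")
  }
  if (all(is.na(studies$loghr_os))) {
    abort("All OS estimates are missing: the OS level of the model is unidentified.")
  }
  n_both <- sum(!is.na(studies$loghr_os) & !is.na(studies$loghr_pfs))
  if (n_both < 2) {
    msg <- paste0("Only ", n_both, " study reports both outcomes; the ",
                  "between-study correlation is unidentified.")
    if (!force) abort(paste(msg, "Use `force = TRUE` to proceed anyway."))
    warn(msg)
  }

  fixed_rho_w <- !is.null(priors$rho_w_fixed)
  model <- paste0(
    .brma_model,
    if (fixed_rho_w) "" else
      "  for (i in 1:N) { rho_w[i] ~ dunif(rho_w_lo, rho_w_hi) }\n",
    "}"
  )
  logv <- function(se) ifelse(is.na(se), NA_real_, log(se^2))
  data <- list(
    N = n,
    y_os = studies$loghr_os, y_pfs = studies$loghr_pfs,
    logv_os = logv(studies$se_os), logv_pfs = logv(studies$se_pfs),
    prior_prec_mean = 1 / priors$mean_var,
    prior_prec_tau = 1 / priors$tau_var,
    rho_b_lo = priors$rho_b_bounds[1], rho_b_hi = priors$rho_b_bounds[2],
    logvar_sd_upper = priors$logvar_sd_upper
  )
  if (fixed_rho_w) {
    data$rho_w <- rep_len(priors$rho_w_fixed, n)
  } else {
    data$rho_w_lo <- priors$rho_w_bounds[1]
    data$rho_w_hi <- priors$rho_w_bounds[2]
  }
  params <- c("eta_os", "lambda0", "lambda1", "tau_os", "tau_pfs", "rho_b",
              "psq_pfs", "mu_os", "mu_pfs", "y_os", "y_pfs",
              "s_os", "s_pfs", if (!fixed_rho_w) "rho_w")
  inits <- function(k) {
    out <- list(
      eta_os = mean(studies$loghr_os, na.rm = TRUE),
      lambda0 = mean(studies$loghr_pfs, na.rm = TRUE),
      tau_os = 0.1 + 0.05 * k, tau_pfs = 0.1 + 0.05 * k, rho_b = 0
    )
    if (!fixed_rho_w) out$rho_w <- rep(0, n)
    out
  }
  res <- run_jags(model, data, params, mcmc, inits)

  core <- c("eta_os", "lambda0", "lambda1", "tau_os", "tau_pfs", "rho_b",
            "psq_pfs")
  smry <- add_hr_scale(summarise_draws(res$draws, core))
  converged <- check_convergence(
    res$diagnostics[res$diagnostics$param %in% core, ], "BRMA")

  miss <- dplyr::bind_rows(
    tibble(idx = which(is.na(studies$loghr_os)), outcome = "os"),
    tibble(idx = which(is.na(studies$loghr_pfs)), outcome = "pfs")
  )
  pred_draws <- NULL
  predictions <- tibble()
  if (nrow(miss)) {
    pred_draws <- purrr::pmap(miss, function(idx, outcome) {
      node <- sprintf("y_%s[%d]", outcome, idx)
      se_node <- sprintf("s_%s[%d]", outcome, idx)
      tibble(
        .draw = res$draws$.draw,
        study_id = studies$study_id[idx], outcome = outcome,
        value = res$draws[[node]], pred_se = res$draws[[se_node]]
      )
    }) |> purrr::list_rbind()
    predictions <- pred_draws |>
      group_by(.data$study_id, .data$outcome) |>
      summarise(
        mean = mean(.data$value), sd = sd(.data$value),
        median = median(.data$value),
        q2.5 = unname(quantile(.data$value, 0.025)),
        q97.5 = unname(quantile(.data$value, 0.975)),
        pred_se_mean = mean(.data$pred_se),
        .groups = "drop"
      ) |>
      add_hr_scale()
  }

  structure(
    list(draws = res$draws, summary = smry, predictions = predictions,
         pred_draws = pred_draws, diagnostics = res$diagnostics,
         converged = converged, studies = studies, priors = priors,
         mcmc = mcmc),
    class = "brma_fit"
  )
}

#' @export
print.brma_fit <- function(x, ...) {
  cat(sprintf("Bivariate random-effects meta-analysis (%d studies)\n",
              nrow(x$studies)))
  for (p in c("eta_os", "lambda0", "tau_os", "tau_pfs", "rho_b")) {
    r <- x$summary[x$summary$param == p, ]
    cat(sprintf("  %-8s median %7.3f (95%% CrI %7.3f, %7.3f)\n",
                p, r$median, r$q2.5, r$q97.5))
  }
  if (nrow(x$predictions)) {
    cat("Predicted missing observed effects:\n")
    for (i in seq_len(nrow(x$predictions))) {
      r <- x$predictions[i, ]
      cat(sprintf("  %s (%s): HR %.3f (95%% CrI %.3f-%.3f)\n",
                  r$study_id, toupper(r$outcome), r$hr, r$hr_q2.5,
                  r$hr_q97.5))
    }
  }
  if (!x$converged) cat("  [warning: not all nodes converged]\n")
  invisible(x)
}

#' @export
tidy.brma_fit <- function(x, ...) x$summary

#' @export
glance.brma_fit <- function(x, ...) {
  tibble(
    n_studies = nrow(x$studies),
    n_missing = if (is.null(x$pred_draws)) 0L else
      nrow(dplyr::distinct(x$pred_draws, .data$study_id, .data$outcome)),
    n_draws = nrow(x$draws),
    min_ess = min(x$diagnostics$ess),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    converged = x$converged
  )
}
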