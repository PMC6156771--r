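#' Simulate a study-level bivariate evidence set
#'
#' Draws study-level true effects from a between-study bivariate normal
#' (means `eta_os`, `eta_pfs`; SDs `tau_os`, `tau_pfs`; correlation `rho_b`)
#' and observed effects from the within-study bivariate normal with drawn
#' standard errors and within-study correlation `rho_w`. Entries listed in
#' `missing` are blanked afterwards, emulating unreported outcomes with known
#' ground truth.
#'
#' Default parameter values describe a small hormone-refractory prostate
#' cancer evidence base: modest OS benefit, stronger and more heterogeneous
#' PFS benefit, strong positive between-study correlation between the two.
#'
#' @param n_studies Number of studies.
#' @param eta_os,eta_pfs True pooled log hazard ratios.
#' @param tau_os,tau_pfs Between-study SDs (>= 0).
#' @param rho_b Between-study correlation in `[-1, 1]`.
#' @param rho_w Within-study correlation(s); scalar or length `n_studies`.
#' @param se_range Interval from which within-study SEs are drawn uniformly.
#' @param missing Optional data frame with columns `study` (row index) and
#'   `outcome` (`"os"` or `"pfs"`) naming entries to blank.
#' @param ref,comp Treatment codes stamped on every row.
#' @param seed Integer seed; the draw is deterministic given the seed and
#'   does not disturb the global RNG state.
#' @return A `study_table` tibble with attribute `truth`: a tibble of the
#'   generating `mu_os`, `mu_pfs` and the pre-blanking observed values.
#' @examples
#' simulate_study_set(n_studies = 4, seed = 1)
#' @export
simulate_study_set <- function(n_studies = 4,
                               eta_os = log(0.90),
                               eta_pfs = log(0.64),
                               tau_os = 0.15,
                               tau_pfs = 0.30,
                               rho_b = 0.8,
                               rho_w = 0.4,
                               se_range = c(0.10, 0.22),
                               missing = NULL,
                               ref = "P", comp = "M+P",
                               seed = NULL) {
  stopifnot(n_studies >= 1, tau_os >= 0, tau_pfs >= 0,
            abs(rho_b) <= 1, all(abs(rho_w) <= 1),
            length(se_range) == 2, all(se_range > 0),
            se_range[1] <= se_range[2])
  rho_w <- rep_len(rho_w, n_studies)
  draw <- function() {
    z1 <- rnorm(n_studies)
    z2 <- rnorm(n_studies)
    mu_os <- eta_os + tau_os * z1
    mu_pfs <- eta_pfs + tau_pfs * (rho_b * z1 + sqrt(1 - rho_b^2) * z2)
    se_os <- runif(n_studies, se_range[1], se_range[2])
    se_pfs <- runif(n_studies, se_range[1], se_range[2])
    e1 <- rnorm(n_studies)
    e2 <- rnorm(n_studies)
    y_os <- mu_os + se_os * e1
    y_pfs <- mu_pfs + se_pfs * (rho_w * e1 + sqrt(1 - rho_w^2) * e2)
    tibble(
      study_id = sprintf("SIM%02d", seq_len(n_studies)),
      ref = ref, comp = comp,
      loghr_os = y_os, se_os = se_os,
      loghr_pfs = y_pfs, se_pfs = se_pfs,
      mu_os = mu_os, mu_pfs = mu_pfs
    )
  }
  full <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  truth <- full
  out <- full[, c("study_id", "ref", "comp", "loghr_os", "se_os",
                  "loghr_pfs", "se_pfs")]
  if (!is.null(missing) && nrow(as.data.frame(missing))) {
    missing <- as.data.frame(missing)
    stopifnot(all(c("study", "outcome") %in% names(missing)),
              all(missing$study %in% seq_len(n_studies)),
              all(missing$outcome %in% c("os", "pfs")))
    for (k in seq_len(nrow(missing))) {
      i <- missing$study[k]
      out[[paste0("loghr_", missing$outcome[k])]][i] <- NA_real_
      out[[paste0("se_", missing$outcome[k])]][i] <- NA_real_
    }
  }
  out <- validate_study_table(out)
  attr(out, "truth") <- truth
  out
}

#' Simulate Weibull survival IPD with right censoring
#'
#' Reference-arm times follow `S(t) = exp(-rate * t^shape)`; comparator
#' times follow `S(t)^hr`, i.e. exact proportional hazards on the Weibull.
#' Times beyond `censor_time` are recorded as censored at `censor_time`.
#'
#' @param n_per_arm Patients per arm.
#' @param shape,rate Weibull parameters of the reference arm, in the
#'   `S(t) = exp(-rate * t^shape)` convention with `t` in months.
#' @param hr Hazard ratio applied to the comparator arm (> 0).
#' @param censor_time Administrative censoring horizon in months (`Inf` for
#'   none).
#' @param arms Length-2 character vector of arm codes (reference first).
#' @param study_id Study label stamped on every row.
#' @param seed Integer seed (deterministic, RNG-state preserving).
#' @return An IPD tibble with columns `study_id, arm, time_months, event`.
#' @examples
#' simulate_ipd(50, shape = 1.2, rate = 0.02, hr = 0.7, seed = 1)
#' @export
simulate_ipd <- function(n_per_arm, shape, rate, hr = 1,
                         censor_time = Inf, arms = c("ref", "comp"),
                         study_id = "SIM", seed = NULL) {
  stopifnot(n_per_arm >= 1, shape > 0, rate > 0, hr > 0, censor_time > 0,
            length(arms) == 2)
  draw <- function() {
    t_ref <- (-log(runif(n_per_arm)) / rate)^(1 / shape)
    t_comp <- (-log(runif(n_per_arm)) / (rate * hr))^(1 / shape)
    tibble(
      study_id = study_id,
      arm = rep(arms, each = n_per_arm),
      time_true = c(t_ref, t_comp)
    )
  }
  out <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  out$event <- as.integer(out$time_true <= censor_time)
  out$time_months <- pmin(out$time_true, censor_time)
  out[, c("study_id", "arm", "time_months", "event")]
}
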