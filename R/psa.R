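#' Probabilistic sensitivity analysis of the Markov decision model
#'
#' Propagates parameter uncertainty through the cohort model by Monte
#' Carlo: per draw, Weibull parameters of the primary transition are drawn
#' from a bivariate normal on `(log rate, log shape)`, utilities from
#' normal distributions truncated to `[0, 1]`, costs with stated
#' uncertainty from moment-matched gamma distributions, the follow-up cost
#' split uniformly on its stated range, and treatment effects from the
#' posterior draws supplied in `hr_draws` -- so evidence-synthesis
#' uncertainty (including a predicted missing effect) flows into the
#' decision model as full posterior distributions, not summaries.
#'
#' For the 3-state model the progressed-to-dead probability is re-solved
#' per draw from the drawn overall-survival and progression-free Weibull
#' means ([solve_pd_death_tp()]), so it inherits their uncertainty.
#'
#' @param markov_inputs Decision-model inputs in the layout of
#'   `hta_fixture()$markov_inputs`.
#' @param hr_draws Tibble with columns `draw`, `treatment`, `loghr`: per
#'   -draw log hazard ratios versus the baseline treatment (baseline rows
#'   may be omitted and are taken as 0).
#' @param model `"two_state"` or `"three_state"`.
#' @param n_draws Number of PSA iterations; `hr_draws` are recycled by
#'   sampling with replacement if fewer draws are supplied.
#' @param seed Integer seed for the PSA-level random draws.
#' @return A `psa_result`: tibble with columns `draw`, `treatment`,
#'   `cost`, `qaly` and attribute `settings`.
#' @export
run_psa <- function(markov_inputs, hr_draws,
                    model = c("three_state", "two_state"),
                    n_draws = 2000, seed = 1) {
  model <- match.arg(model)
  mi <- markov_inputs
  treatments <- mi$treatments$codes
  baseline <- mi$treatments$baseline
  hr_draws <- as_tibble(hr_draws)
  stopifnot(all(c("draw", "treatment", "loghr") %in% names(hr_draws)))
  extra <- setdiff(unique(hr_draws$treatment), treatments)
  if (length(extra)) {
    abort(paste0("Unknown treatment(s) in `hr_draws`: ",
                 paste(extra, collapse = ", ")))
  }
  # Hazard ratios beyond 10-fold are not clinically meaningful and can
  # push a cycle transition probability past feasibility; heavy posterior
  # tails are truncated here, audibly, rather than clipped inside the
  # Markov engine.
  n_extreme <- sum(abs(hr_draws$loghr) > log(10))
  if (n_extreme > 0) {
    warn(sprintf(
      "Truncating %d of %d treatment-effect draws to hazard ratios in [1/10, 10].",
      n_extreme, nrow(hr_draws)))
    hr_draws$loghr <- pmin(pmax(hr_draws$loghr, -log(10)), log(10))
  }

  wb_key <- if (model == "two_state") "os" else "pfs"
  draws <- withr::with_seed(seed, {
    idx_pool <- unique(hr_draws$draw)
    idx <- sample(idx_pool, n_draws, replace = TRUE)
    wb_primary <- draw_weibull(mi$weibull[[wb_key]], n_draws)
    wb_os <- if (model == "three_state") {
      draw_weibull(mi$weibull$os, n_draws)
    }
    u <- list(
      surviving = rtrunc_norm01(n_draws, mi$utilities$surviving),
      pd = rtrunc_norm01(n_draws, mi$utilities$pd),
      other_causes = rtrunc_norm01(n_draws, mi$utilities$other_causes),
      alive = rtrunc_norm01(n_draws, mi$utilities$alive_two_state)
    )
    fu <- rgamma_moment(n_draws, mi$costs$followup_monthly)
    term <- rgamma_moment(n_draws, mi$costs$terminal)
    frac <- runif(n_draws, mi$costs$followup_pd_fraction[1],
                  mi$costs$followup_pd_fraction[2])
    list(idx = idx, wb_primary = wb_primary, wb_os = wb_os, u = u,
         fu = fu, term = term, frac = frac)
  })

  hr_wide <- matrix(0, nrow = length(unique(hr_draws$draw)),
                    ncol = length(treatments),
                    dimnames = list(NULL, treatments))
  rownames(hr_wide) <- as.character(sort(unique(hr_draws$draw)))
  for (tr in setdiff(unique(hr_draws$treatment), baseline)) {
    sub <- hr_draws[hr_draws$treatment == tr, ]
    hr_wide[as.character(sub$draw), tr] <- sub$loghr
  }

  res <- vector("list", n_draws)
  for (j in seq_len(n_draws)) {
    loghr_j <- hr_wide[as.character(draws$idx[j]), ]
    hr_j <- exp(loghr_j)
    hr_j[baseline] <- 1
    pd_tp <- NULL
    if (model == "three_state") {
      os_mean <- weibull_mean(draws$wb_os$shape[j], draws$wb_os$rate[j])
      pfs_mean <- weibull_mean(draws$wb_primary$shape[j],
                               draws$wb_primary$rate[j])
      pd_tp <- solve_pd_death_tp(
        os_mean = max(os_mean, pfs_mean + 0.5),
        pfs_mean = pfs_mean,
        p_pc_death = mi$transition$p_pc_death,
        m_other = mi$transition$m_other_months,
        cycle_months = mi$markov$cycle_months
      )
    }
    spec <- markov_spec(
      model = model,
      weibull = list(shape = draws$wb_primary$shape[j],
                     rate = draws$wb_primary$rate[j]),
      hr = hr_j,
      other_cause_tp = mi$transition$other_cause_tp,
      pd_death_tp = pd_tp,
      n_cycles = mi$markov$cycles,
      cycle_months = mi$markov$cycle_months,
      cohort = mi$markov$cohort,
      discount_rate = mi$markov$discount_rate,
      discount_start_cycle = mi$markov$discount_start_cycle
    )
    utilities <- list(surviving = draws$u$surviving[j],
                      pd = draws$u$pd[j],
                      other_causes = draws$u$other_causes[j],
                      alive = draws$u$alive[j])
    res[[j]] <- vapply(treatments, function(tr) {
      costs <- list(acquisition = mi$costs$acquisition[[tr]],
                    followup_monthly = draws$fu[j],
                    followup_pd_fraction = draws$frac[j],
                    terminal = draws$term[j])
      cohort_cost_qaly(spec, tr, costs, utilities)
    }, c(cost = 0, qaly = 0))
  }
  out <- tibble(
    draw = rep(seq_len(n_draws), each = length(treatments)),
    treatment = rep(treatments, times = n_draws),
    cost = unlist(lapply(res, function(m) m["cost", ])),
    qaly = unlist(lapply(res, function(m) m["qaly", ]))
  )
  class(out) <- c("psa_result", class(out))
  attr(out, "settings") <- list(model = model, n_draws = n_draws,
                                seed = seed, baseline = baseline)
  out
}

# Bivariate normal draw of Weibull parameters on the log scale.
draw_weibull <- function(wb, n) {
  s <- c(wb$sd_log_rate %||% 0, wb$sd_log_shape %||% 0)
  r <- wb$corr_log %||% 0
  z1 <- rnorm(n)
  z2 <- r * z1 + sqrt(1 - r^2) * rnorm(n)
  list(rate = exp(log(wb$rate) + s[1] * z1),
       shape = exp(log(wb$shape) + s[2] * z2))
}

# Normal truncated to [0, 1] by inverse-CDF sampling.
rtrunc_norm01 <- function(n, par) {
  m <- par$mean
  s <- par$se %||% 0
  if (s == 0) return(rep(m, n))
  plo <- pnorm((0 - m) / s)
  phi <- pnorm((1 - m) / s)
  m + s * qnorm(runif(n, plo, phi))
}

# Gamma moment-matched to (mean, se); degenerate at the mean when se = 0.
rgamma_moment <- function(n, par) {
  m <- par$mean
  s <- par$se %||% 0
  if (s == 0) return(rep(m, n))
  shape <- (m / s)^2
  rgamma(n, shape = shape, rate = shape / m)
}

#' @export
tidy.psa_result <- function(x, ...) {
  as_tibble(x) |>
    group_by(.data$treatment) |>
    summarise(
      mean_cost = mean(.data$cost),
      cost_q2.5 = unname(quantile(.data$cost, 0.025)),
      cost_q97.5 = unname(quantile(.data$cost, 0.975)),
      mean_qaly = mean(.data$qaly),
      qaly_q2.5 = unname(quantile(.data$qaly, 0.025)),
      qaly_q97.5 = unname(quantile(.data$qaly, 0.975)),
      .groups = "drop"
    )
}

#' @export
glance.psa_result <- function(x, ...) {
  s <- attr(x, "settings")
  tibble(model = s$model, n_draws = s$n_draws,
         n_treatments = length(unique(x$treatment)), seed = s$seed)
}
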