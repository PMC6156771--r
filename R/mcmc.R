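#' MCMC sampler settings
#'
#' Run lengths default to the evidence-synthesis settings used throughout
#' the package: 30,000 iterations per chain of which the first 15,000 are
#' discarded as burn-in, on 2 chains.
#'
#' @param n_iter Total iterations per chain (burn-in included).
#' @param n_burnin Burn-in iterations discarded per chain.
#' @param n_chains Number of chains (>= 2 enables split-chain diagnostics).
#' @param thin Thinning interval.
#' @param seed Integer seed controlling all chains.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(n_iter = 30000, n_burnin = 15000, n_chains = 2,
                         thin = 1, seed = 1) {
  stopifnot(n_iter > n_burnin, n_burnin >= 0, n_chains >= 1, thin >= 1)
  structure(
    list(n_iter = as.integer(n_iter), n_burnin = as.integer(n_burnin),
         n_chains = as.integer(n_chains), thin = as.integer(thin),
         seed = as.integer(seed)),
    class = "mcmc_control"
  )
}

# Derive a valid 32-bit JAGS RNG seed for chain `k` from a user seed.
.chain_seed <- function(seed, k) {
  s <- (abs(as.numeric(seed)) %% 2147480000) + 7919 * k
  as.integer((s %% 2147483646) + 1)
}

# Run a JAGS model and return posterior draws as a tibble plus diagnostics.
# `inits` is a function(chain) returning a named list of initial values.
run_jags <- function(model_string, data, params, mcmc,
                     inits = function(chain) list()) {
  stopifnot(inherits(mcmc, "mcmc_control"))
  init_list <- lapply(seq_len(mcmc$n_chains), function(k) {
    c(inits(k),
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = .chain_seed(mcmc$seed, k)))
  })
  model <- rjags::jags.model(
    textConnection(model_string), data = data, inits = init_list,
    n.chains = mcmc$n_chains, n.adapt = max(500, mcmc$n_burnin %/% 10),
    quiet = TRUE
  )
  if (mcmc$n_burnin > 0) {
    update(model, n.iter = mcmc$n_burnin, progress.bar = "none")
  }
  samples <- rjags::coda.samples(
    model, variable.names = params,
    n.iter = mcmc$n_iter - mcmc$n_burnin, thin = mcmc$thin,
    progress.bar = "none"
  )
  draws <- as_tibble(as.data.frame(as.matrix(samples)))
  n_kept <- nrow(as.matrix(samples[[1]]))
  draws$.chain <- rep(seq_len(mcmc$n_chains), each = n_kept)
  draws$.draw <- seq_len(nrow(draws))
  list(draws = draws, coda = samples,
       diagnostics = mcmc_diagnostics(samples))
}

# Split-interval R-hat (via coda) and effective sample size per node.
# Constant (observed) monitored nodes are dropped from the table.
mcmc_diagnostics <- function(samples) {
  ess <- coda::effectiveSize(samples)
  keep <- names(ess)[vapply(names(ess), function(v) {
    sd(unlist(lapply(samples, function(ch) as.numeric(ch[, v])))) > 1e-12
  }, logical(1))]
  ess <- ess[keep]
  rhat <- rep(NA_real_, length(ess))
  names(rhat) <- names(ess)
  if (length(samples) >= 2 && length(keep)) {
    gd <- try(coda::gelman.diag(samples[, keep, drop = FALSE],
                                autoburnin = FALSE,
                                multivariate = FALSE), silent = TRUE)
    if (!inherits(gd, "try-error")) {
      rhat[keep] <- gd$psrf[, 1]
    }
  }
  tibble(param = names(ess), ess = unname(ess), rhat = unname(rhat))
}

# Shared posterior summary: mean, sd, median, central 95% interval.
summarise_draws <- function(draws, params) {
  params <- intersect(params, names(draws))
  purrr::map(params, function(p) {
    v <- draws[[p]]
    tibble(
      param = p, mean = mean(v), sd = sd(v), median = median(v),
      q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975))
    )
  }) |> purrr::list_rbind()
}

# Attach HR-scale columns to a log-scale summary (exp of the log summaries).
add_hr_scale <- function(summary_tbl) {
  dplyr::mutate(
    summary_tbl,
    hr = exp(.data$median),
    hr_mean = exp(.data$mean),
    hr_q2.5 = exp(.data$q2.5),
    hr_q97.5 = exp(.data$q97.5)
  )
}

check_convergence <- function(diagnostics, where, tol = 1.05) {
  bad <- diagnostics$param[!is.na(diagnostics$rhat) &
                             diagnostics$rhat > tol]
  if (length(bad)) {
    warn(paste0(where, ": split R-hat > ", tol, " for ",
                paste(bad, collapse = ", "),
                "; treat results as unconverged."))
    return(FALSE)
  }
  TRUE
}
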