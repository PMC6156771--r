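# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths.

# Closed-form inverse-variance (common-effect) pooling.
inv_var_pool <- function(y, se) {
  w <- 1 / se^2
  list(mean = sum(w * y) / sum(w), se = 1 / sqrt(sum(w)))
}

# Newton-Raphson on the Breslow partial likelihood for a binary covariate.
# Score/information computed from first principles at each event time.
cox_newton <- function(time, event, z, tol = 1e-10, max_iter = 50) {
  ord <- order(time)
  time <- time[ord]; event <- event[ord]; z <- z[ord]
  beta <- 0
  for (it in seq_len(max_iter)) {
    score <- 0; info <- 0
    ebz <- exp(beta * z)
    # risk set at t: all with time >= t (ties: Breslow uses full risk set)
    for (t_ev in unique(time[event == 1])) {
      at_risk <- time >= t_ev
      d <- sum(event == 1 & time == t_ev)
      dz <- sum(z[event == 1 & time == t_ev])
      s0 <- sum(ebz[at_risk])
      s1 <- sum((z * ebz)[at_risk])
      s2 <- sum((z^2 * ebz)[at_risk])
      score <- score + dz - d * s1 / s0
      info <- info + d * (s2 / s0 - (s1 / s0)^2)
    }
    step <- score / info
    beta <- beta + step
    ebz <- exp(beta * z)
    if (abs(step) < tol) break
  }
  list(loghr = beta, se = 1 / sqrt(info))
}

# Cohort-level stochastic microsimulation with the same per-cycle
# matrices: each state's occupants transition multinomially.
microsim_occupancy <- function(spec, treatment, n_people, seed) {
  set.seed(seed)
  k <- length(spec$states)
  counts <- c(n_people, rep(0, k - 1))
  occ <- matrix(0, spec$n_cycles + 1, k,
                dimnames = list(NULL, spec$states))
  occ[1, ] <- counts
  for (t in seq_len(spec$n_cycles)) {
    m <- build_matrix(spec, treatment, t)
    nxt <- rep(0, k)
    for (s in seq_len(k)) {
      if (counts[s] > 0) {
        nxt <- nxt + as.numeric(stats::rmultinom(1, counts[s], m[s, ]))
      }
    }
    counts <- nxt
    occ[t + 1, ] <- counts
  }
  occ
}

# Short MCMC settings for tests where sampler precision is not the point.
quick_mcmc <- function(seed, n_iter = 4000, n_burnin = 1000, chains = 2) {
  mcmc_control(n_iter, n_burnin, chains, seed = seed)
}
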