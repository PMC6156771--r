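#' Time-dependent Weibull cycle transition probability
#'
#' Probability of the modelled event during cycle `t` (months) conditional
#' on being event-free at the start of the cycle, under
#' `S(t) = exp(-rate * t^shape)`:
#' `1 - S(t)/S(t-1) = 1 - exp(rate * (t-1)^shape - rate * t^shape)`.
#'
#' @param shape,rate Positive Weibull parameters.
#' @param t Cycle index (>= 1); vectorised.
#' @return Transition probability in `(0, 1)`.
#' @examples
#' weibull_cycle_tp(1, 0.05, 1:3) # exponential: constant 0.048771
#' @export
weibull_cycle_tp <- function(shape, rate, t) {
  if (any(shape <= 0) || any(rate < 0)) {
    abort("`shape` must be positive and `rate` non-negative.")
  }
  if (any(t < 1)) abort("Cycle index `t` must be >= 1.")
  1 - exp(rate * (t - 1)^shape - rate * t^shape)
}

#' Apply a hazard ratio to a cycle transition probability
#'
#' Proportional hazards on the cycle survival fraction:
#' `1 - (1 - tp)^hr`.
#'
#' @param tp Transition probability in `[0, 1]`; vectorised.
#' @param hr Positive hazard ratio.
#' @return Adjusted transition probability.
#' @examples
#' apply_hr(0.1, 0.5) # 1 - 0.9^0.5
#' @export
apply_hr <- function(tp, hr) {
  if (any(hr <= 0)) abort("`hr` must be positive.")
  if (any(tp < 0 | tp > 1)) abort("`tp` must lie in [0, 1].")
  1 - (1 - tp)^hr
}

#' Progressed-to-dead transition probability from mean survival times
#'
#' The progressive-disease exit rate is identified by decomposing mean
#' total survival: the mean overall survival time equals the weighted sum
#' of (a) survival through stable disease to progression and then to death
#' and (b) survival from stable disease straight to death from other
#' causes:
#' `os_mean = p_pc_death * (pfs_mean + d_pd) + (1 - p_pc_death) * m_other`.
#' Solving for the mean progressive-disease duration `d_pd` gives the
#' constant per-cycle probability `1 - exp(-cycle_months / d_pd)`.
#'
#' @param os_mean,pfs_mean Mean overall and progression-free survival
#'   (months).
#' @param p_pc_death Proportion of deaths due to the disease (in `[0, 1]`).
#' @param m_other Mean survival time (months) when death occurs from other
#'   causes; required when `p_pc_death < 1`.
#' @param cycle_months Cycle length in months.
#' @return Constant monthly transition probability from the progressive
#'   state to dead.
#' @examples
#' solve_pd_death_tp(18, 6, 1) # d_pd = 12 -> 1 - exp(-1/12)
#' @export
solve_pd_death_tp <- function(os_mean, pfs_mean, p_pc_death,
                              m_other = NULL, cycle_months = 1) {
  stopifnot(os_mean > 0, pfs_mean > 0, p_pc_death >= 0, p_pc_death <= 1,
            cycle_months > 0)
  if (p_pc_death == 0) {
    abort("`p_pc_death` = 0: no deaths pass through the progressive state, so its exit rate is undefined.")
  }
  if (p_pc_death < 1 && is.null(m_other)) {
    abort("`m_other` is required when `p_pc_death` < 1.")
  }
  other <- if (p_pc_death < 1) (1 - p_pc_death) * m_other else 0
  d_pd <- (os_mean - p_pc_death * pfs_mean - other) / p_pc_death
  if (d_pd <= 0) {
    abort(sprintf(
      "Infeasible decomposition: implied mean progressive-disease duration is %.4f months (<= 0).",
      d_pd))
  }
  1 - exp(-cycle_months / d_pd)
}

#' Annual discount factor applied on a monthly cycle grid
#'
#' Costs and utilities are undiscounted during the first year and
#' discounted in annual steps thereafter: the factor is 1 for
#' `t < start_cycle` and `(1 + annual_rate)^(-floor((t - 1) / 12))`
#' afterwards.
#'
#' @param t Cycle index (>= 1); vectorised.
#' @param annual_rate Annual discount rate.
#' @param start_cycle First discounted cycle.
#' @return Discount factor(s) in `(0, 1]`.
#' @examples
#' discount_factor(c(12, 13, 25))
#' @export
discount_factor <- function(t, annual_rate = 0.035, start_cycle = 13) {
  if (any(t < 1)) abort("Cycle index `t` must be >= 1.")
  ifelse(t < start_cycle, 1,
         (1 + annual_rate)^(-floor((t - 1) / 12)))
}

#' Transition-probability-weighted utility of the stable-disease state
#'
#' In each cycle a stable patient stays stable, progresses, or dies of
#' other causes; the state utility is the corresponding convex combination
#' of the surviving, progressive-disease and other-cause-death utilities.
#'
#' @param tp_stay,tp_pd,tp_dead_other Transition probabilities out of the
#'   stable state this cycle; must sum to 1 (vectorised).
#' @param utilities List with numeric elements `surviving`, `pd`,
#'   `other_causes` (means on the EQ-5D scale).
#' @return Utility value(s).
#' @examples
#' u <- list(surviving = 0.770, pd = 0.538, other_causes = 0.564)
#' u_std_weighted(0.9, 0.095, 0.005, u)
#' @export
u_std_weighted <- function(tp_stay, tp_pd, tp_dead_other, utilities) {
  s <- tp_stay + tp_pd + tp_dead_other
  if (any(abs(s - 1) > 1e-9)) {
    abort("Stable-state transition probabilities must sum to 1.")
  }
  tp_stay * utilities$surviving + tp_pd * utilities$pd +
    tp_dead_other * utilities$other_causes
}

#' Specify a 2-state or 3-state Markov cohort model
#'
#' The 2-state model distributes the cohort over Alive/Dead with a
#' time-dependent Weibull transition (overall survival of the baseline
#' treatment, scaled per treatment by its OS hazard ratio). The 3-state
#' model distributes it over StableDisease/ProgressiveDisease/Dead: the
#' stable-to-progressed transition is Weibull (progression-free survival,
#' scaled by the PFS hazard ratio), a fixed other-cause death probability
#' leaves the stable state each cycle, and the progressed-to-dead
#' probability is constant (see [solve_pd_death_tp()]).
#'
#' @param model `"two_state"` or `"three_state"`.
#' @param weibull List with `shape` and `rate` of the baseline-treatment
#'   Weibull governing the primary transition (OS for 2-state, PFS for
#'   3-state).
#' @param hr Named vector of hazard ratios versus the baseline treatment
#'   (baseline entry 1), applied to the primary transition.
#' @param other_cause_tp Per-cycle other-cause death probability out of the
#'   stable state (3-state only).
#' @param pd_death_tp Constant progressed-to-dead probability (3-state
#'   only).
#' @param n_cycles,cycle_months,cohort Cycle count, cycle length (months)
#'   and cohort size.
#' @param discount_rate,discount_start_cycle Annual discount rate and first
#'   discounted cycle.
#' @return A list of class `markov_spec`.
#' @export
markov_spec <- function(model = c("three_state", "two_state"),
                        weibull, hr,
                        other_cause_tp = 0.005, pd_death_tp = NULL,
                        n_cycles = 180, cycle_months = 1, cohort = 10000,
                        discount_rate = 0.035, discount_start_cycle = 13) {
  model <- match.arg(model)
  stopifnot(is.list(weibull), weibull$shape > 0, weibull$rate > 0,
            all(hr > 0), !is.null(names(hr)),
            n_cycles >= 1, cycle_months > 0, cohort > 0,
            discount_rate >= 0, discount_rate < 1,
            other_cause_tp >= 0, other_cause_tp <= 1)
  if (model == "three_state") {
    if (is.null(pd_death_tp)) {
      abort("`pd_death_tp` is required for the three-state model.")
    }
    stopifnot(pd_death_tp >= 0, pd_death_tp <= 1)
  }
  states <- if (model == "two_state") c("Alive", "Dead") else
    c("StableDisease", "ProgressiveDisease", "Dead")
  structure(
    list(model = model, states = states, weibull = weibull, hr = hr,
         other_cause_tp = other_cause_tp, pd_death_tp = pd_death_tp,
         n_cycles = as.integer(n_cycles), cycle_months = cycle_months,
         cohort = cohort, discount_rate = discount_rate,
         discount_start_cycle = as.integer(discount_start_cycle)),
    class = "markov_spec"
  )
}

#' Cycle-specific transition matrix of a Markov specification
#'
#' Rows are constructed directly from the transition probabilities (never
#' renormalized post hoc); an infeasible row (probabilities summing beyond
#' 1) is an error, since it signals a mis-specified Weibull or hazard
#' ratio rather than something to clip silently.
#'
#' @param spec A [markov_spec()].
#' @param treatment Treatment code (a name of `spec$hr`).
#' @param t Cycle index (>= 1).
#' @return A square transition matrix with `spec$states` dimnames.
#' @export
build_matrix <- function(spec, treatment, t) {
  stopifnot(inherits(spec, "markov_spec"))
  if (!treatment %in% names(spec$hr)) {
    abort(paste0("Unknown treatment '", treatment, "'."))
  }
  tp <- apply_hr(
    weibull_cycle_tp(spec$weibull$shape, spec$weibull$rate, t),
    spec$hr[[treatment]]
  )
  if (spec$model == "two_state") {
    m <- matrix(c(1 - tp, tp,
                  0, 1), nrow = 2, byrow = TRUE,
                dimnames = list(spec$states, spec$states))
  } else {
    stay <- 1 - tp - spec$other_cause_tp
    if (stay < 0) {
      abort(sprintf(
        "Infeasible stable-state row at cycle %d: progression tp %.4f plus other-cause tp %.4f exceeds 1.",
        t, tp, spec$other_cause_tp))
    }
    m <- matrix(c(stay, tp, spec$other_cause_tp,
                  0, 1 - spec$pd_death_tp, spec$pd_death_tp,
                  0, 0, 1), nrow = 3, byrow = TRUE,
                dimnames = list(spec$states, spec$states))
  }
  m
}

#' Run the Markov cohort simulation
#'
#' Starts the whole cohort in the first living state and applies the
#' cycle-`t` matrix for `t = 1, ..., n_cycles`, recording state occupancy
#' and per-transition entry counts.
#'
#' @param spec A [markov_spec()].
#' @param treatment Treatment code.
#' @return An object of class `state_trace`: a list with `occupancy`
#'   (tibble `cycle` 0..n by `state`, persons), `entries` (tibble `cycle`,
#'   `from`, `to`, `count`), `std_tp` (per-cycle stable-state transition
#'   probabilities, 3-state only), `spec`, `treatment`.
#' @export
run_cohort <- function(spec, treatment) {
  core <- cohort_core(spec, treatment)
  n <- spec$n_cycles
  tcy <- seq_len(n)
  if (spec$model == "two_state") {
    occ <- cbind(Alive = core$alive0, Dead = spec$cohort - core$alive0)
    entries <- tibble(cycle = tcy, from = "Alive", to = "Dead",
                      count = core$dead_in)
    std_tp <- NULL
  } else {
    occ <- cbind(StableDisease = core$std0, ProgressiveDisease = core$pd0,
                 Dead = spec$cohort - core$std0 - core$pd0)
    entries <- bind_rows(
      tibble(cycle = tcy, from = "StableDisease", to = "ProgressiveDisease",
             count = core$to_pd),
      tibble(cycle = tcy, from = "StableDisease", to = "Dead",
             count = core$std_to_dead),
      tibble(cycle = tcy, from = "ProgressiveDisease", to = "Dead",
             count = core$pd_to_dead)
    ) |> arrange(.data$cycle)
    entries <- entries[entries$count > 0, ]
    std_tp <- tibble(cycle = tcy, stay = core$stay, pd = core$tp,
                     dead_other = spec$other_cause_tp)
  }
  occupancy <- as_tibble(occ) |> mutate(cycle = 0:n, .before = 1)
  structure(
    list(occupancy = occupancy, entries = entries,
         dead_entries = core$dead_in, std_tp = std_tp, spec = spec,
         treatment = treatment),
    class = "state_trace"
  )
}

# Single source of the cohort arithmetic: per-cycle probabilities exactly
# as build_matrix() composes them, occupancy by cumulative products /
# first-order recursion. Returns plain vectors (index 1 = cycle 0 for the
# *0 occupancy vectors, cycle t for flows at cycle t).
cohort_core <- function(spec, treatment) {
  stopifnot(inherits(spec, "markov_spec"))
  if (!treatment %in% names(spec$hr)) {
    abort(paste0("Unknown treatment '", treatment, "'."))
  }
  n <- spec$n_cycles
  tp <- apply_hr(
    weibull_cycle_tp(spec$weibull$shape, spec$weibull$rate, seq_len(n)),
    spec$hr[[treatment]]
  )
  if (spec$model == "two_state") {
    alive <- spec$cohort * cumprod(1 - tp)
    prev_alive <- c(spec$cohort, alive[-n])
    list(tp = tp, alive0 = c(spec$cohort, alive),
         dead_in = prev_alive * tp)
  } else {
    stay <- 1 - tp - spec$other_cause_tp
    if (any(stay < 0)) {
      t_bad <- which(stay < 0)[1]
      abort(sprintf(
        "Infeasible stable-state row at cycle %d: progression tp %.4f plus other-cause tp %.4f exceeds 1.",
        t_bad, tp[t_bad], spec$other_cause_tp))
    }
    std <- spec$cohort * cumprod(stay)
    prev_std <- c(spec$cohort, std[-n])
    to_pd <- prev_std * tp
    std_to_dead <- prev_std * spec$other_cause_tp
    pd <- numeric(n)
    prev_pd <- 0
    for (t in seq_len(n)) {
      pd[t] <- prev_pd * (1 - spec$pd_death_tp) + to_pd[t]
      prev_pd <- pd[t]
    }
    pd_to_dead <- c(0, pd[-n]) * spec$pd_death_tp
    list(tp = tp, stay = stay, std0 = c(spec$cohort, std),
         pd0 = c(0, pd), to_pd = to_pd, std_to_dead = std_to_dead,
         pd_to_dead = pd_to_dead, dead_in = std_to_dead + pd_to_dead)
  }
}

# Fast PSA path: discounted per-patient cost/QALY straight from
# cohort_core(), bypassing the tibble-based trace. Must stay numerically
# identical to expected_cost_qaly(run_cohort(...), ...); a regression test
# asserts this.
cohort_cost_qaly <- function(spec, treatment, costs, utilities) {
  core <- cohort_core(spec, treatment)
  disc <- discount_factor(seq_len(spec$n_cycles), spec$discount_rate,
                          spec$discount_start_cycle)
  if (spec$model == "two_state") {
    alive <- core$alive0[-1]
    cycle_cost <- alive * costs$followup_monthly * spec$cycle_months +
      core$dead_in * costs$terminal
    cycle_qaly <- alive * utilities$alive * spec$cycle_months / 12
  } else {
    std <- core$std0[-1]
    pd <- core$pd0[-1]
    fu <- costs$followup_monthly * spec$cycle_months
    f <- costs$followup_pd_fraction
    cycle_cost <- std * fu * (1 - f) + pd * fu * f +
      core$dead_in * costs$terminal
    u_std <- core$stay * utilities$surviving + core$tp * utilities$pd +
      spec$other_cause_tp * utilities$other_causes
    cycle_qaly <- (std * u_std + pd * utilities$pd) *
      spec$cycle_months / 12
  }
  c(cost = costs$acquisition + sum(cycle_cost * disc) / spec$cohort,
    qaly = sum(cycle_qaly * disc) / spec$cohort)
}

#' @export
print.state_trace <- function(x, ...) {
  cat(sprintf("Markov %s trace: %s, %d cycles, cohort %g\n",
              x$spec$model, x$treatment, x$spec$n_cycles, x$spec$cohort))
  print(utils::head(x$occupancy, 4))
  invisible(x)
}

#' Discounted per-patient cost and QALY of a cohort trace
#'
#' Each cycle accrues (a) occupancy-weighted state costs -- follow-up cost
#' split between the stable and progressed states by `followup_pd_fraction`
#' in the 3-state model -- plus a one-off terminal-care cost on each entry
#' to Dead, and (b) occupancy-weighted state utilities times the cycle
#' length in years, with the stable-disease utility weighted by that
#' cycle's transition probabilities ([u_std_weighted()]). Both streams are
#' discounted with [discount_factor()] and divided by the cohort size; the
#' treatment acquisition cost is charged once, undiscounted, at the start.
#' No half-cycle correction is applied (end-of-cycle accrual).
#'
#' @param trace A [run_cohort()] result.
#' @param costs List with `acquisition` (one-off, this treatment),
#'   `followup_monthly`, `followup_pd_fraction` (3-state), `terminal`.
#' @param utilities List with `surviving`, `pd`, `other_causes` (3-state)
#'   or `alive` (2-state) mean utilities.
#' @return A one-row tibble with `cost` and `qaly` per patient.
#' @export
expected_cost_qaly <- function(trace, costs, utilities) {
  stopifnot(inherits(trace, "state_trace"))
  spec <- trace$spec
  tcy <- seq_len(spec$n_cycles)
  disc <- discount_factor(tcy, spec$discount_rate,
                          spec$discount_start_cycle)
  occ <- trace$occupancy[trace$occupancy$cycle >= 1, ]
  dead_in <- trace$dead_entries

  if (spec$model == "two_state") {
    alive <- occ$Alive
    cycle_cost <- alive * costs$followup_monthly * spec$cycle_months +
      dead_in * costs$terminal
    cycle_qaly <- alive * utilities$alive * spec$cycle_months / 12
  } else {
    f <- costs$followup_pd_fraction
    std <- occ$StableDisease
    pd <- occ$ProgressiveDisease
    fu <- costs$followup_monthly * spec$cycle_months
    cycle_cost <- std * fu * (1 - f) + pd * fu * f +
      dead_in * costs$terminal
    u_std <- u_std_weighted(trace$std_tp$stay, trace$std_tp$pd,
                            trace$std_tp$dead_other, utilities)
    cycle_qaly <- (std * u_std + pd * utilities$pd) *
      spec$cycle_months / 12
  }
  tibble(
    cost = costs$acquisition + sum(cycle_cost * disc) / spec$cohort,
    qaly = sum(cycle_qaly * disc) / spec$cohort
  )
}
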