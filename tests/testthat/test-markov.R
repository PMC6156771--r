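fixture_spec <- function(model = "three_state", n_cycles = 180,
                         hr = c("M+P" = 1, "P" = 1.5, "D+P" = 0.62),
                         other_cause_tp = 0.005) {
  markov_spec(
    model = model,
    weibull = if (model == "three_state") {
      list(shape = 1.10, rate = 0.096574)
    } else {
      list(shape = 1.25, rate = 0.018695)
    },
    hr = hr, other_cause_tp = other_cause_tp,
    pd_death_tp = if (model == "three_state") 0.0637,
    n_cycles = n_cycles
  )
}

test_that("Weibull cycle probabilities match closed forms", {
  # exponential is memoryless: constant cycle probability
  expect_equal(weibull_cycle_tp(1, 0.05, c(1, 7, 100)),
               rep(1 - exp(-0.05), 3))
  expect_equal(round(weibull_cycle_tp(1, 0.05, 3), 6), 0.048771)
  expect_equal(round(weibull_cycle_tp(2, 0.01, 5), 6), 0.086069)
  expect_equal(weibull_cycle_tp(1.3, 0, 5), 0)
  expect_error(weibull_cycle_tp(-1, 0.05, 1), "positive")
  expect_error(weibull_cycle_tp(1, 0.05, 0), ">= 1")
})

test_that("hazard ratios act on the cycle survival fraction", {
  expect_equal(apply_hr(0.1, 1), 0.1)
  expect_equal(round(apply_hr(0.1, 0.5), 6), 0.051317)
  expect_equal(apply_hr(1, 0.5), 1)
  expect_equal(apply_hr(0, 2), 0)
  # hr < 1 strictly decreases every non-degenerate probability
  tp <- seq(0.01, 0.99, by = 0.07)
  expect_true(all(apply_hr(tp, 0.7) < tp))
  expect_true(all(apply_hr(tp, 1.3) > tp))
  expect_error(apply_hr(0.1, -2), "positive")
})

test_that("progressed-to-dead probability solves the survival decomposition", {
  expect_equal(round(solve_pd_death_tp(18, 6, 1), 5), 0.07996)
  expect_equal(solve_pd_death_tp(18, 6, 1), 1 - exp(-1 / 12))
  # weighting by non-disease deaths
  expect_equal(solve_pd_death_tp(20.7, 8, 0.93, m_other = 12),
               1 - exp(-1 / ((20.7 - 0.93 * 8 - 0.07 * 12) / 0.93)))
  expect_error(solve_pd_death_tp(6, 6, 1), "Infeasible")
  expect_error(solve_pd_death_tp(18, 6, 0.9), "m_other")
  expect_error(solve_pd_death_tp(18, 6, 0), "undefined")
})

test_that("discount factors follow annual steps starting at cycle 13", {
  expect_equal(discount_factor(12), 1)
  expect_equal(round(discount_factor(13), 6), 0.966184)
  expect_equal(round(discount_factor(25), 6), 0.933511)
  expect_equal(discount_factor(1:12), rep(1, 12))
  expect_equal(discount_factor(24), 1 / 1.035)
  expect_equal(discount_factor(37), 1.035^-3)
})

test_that("stable-state utility is the tp-weighted average", {
  u <- list(surviving = 0.770, pd = 0.538, other_causes = 0.564)
  expect_equal(u_std_weighted(1, 0, 0, u), 0.770)
  expect_equal(u_std_weighted(0, 1, 0, u), 0.538)
  expect_equal(round(u_std_weighted(0.9, 0.095, 0.005, u), 5), 0.74693)
  expect_error(u_std_weighted(0.9, 0.05, 0.005, u), "sum to 1")
})

test_that("transition matrices have valid rows and an absorbing dead state", {
  spec <- fixture_spec()
  for (t in c(1, 60, 180)) {
    m <- build_matrix(spec, "D+P", t)
    expect_equal(unname(rowSums(m)), rep(1, 3), tolerance = 1e-12)
    expect_true(all(m >= 0))
    expect_equal(unname(m[3, ]), c(0, 0, 1))
    expect_equal(unname(m[1, 3]), 0.005)
  }
  m2 <- build_matrix(fixture_spec("two_state"), "P", 10)
  expect_equal(unname(rowSums(m2)), rep(1, 2), tolerance = 1e-12)
  expect_equal(unname(m2[2, ]), c(0, 1))
  # infeasible rows error instead of being clipped
  bad <- fixture_spec(hr = c("M+P" = 1, "X" = 500))
  expect_error(run_cohort(bad, "X"), "Infeasible")
})

test_that("cohort traces conserve mass and accumulate deaths monotonically", {
  for (model in c("two_state", "three_state")) {
    spec <- fixture_spec(model)
    tr <- run_cohort(spec, "D+P")
    occ <- tr$occupancy
    tot <- rowSums(occ[, spec$states])
    expect_equal(tot, rep(10000, 181), tolerance = 1e-9)
    expect_true(all(diff(occ$Dead) >= -1e-9))
    expect_true(all(as.matrix(occ[, spec$states]) >= -1e-12))
    expect_equal(sum(tr$dead_entries), occ$Dead[181], tolerance = 1e-9)
  }
})

test_that("the cohort engine matches the transition-matrix power oracle", {
  spec <- fixture_spec(n_cycles = 40)
  for (trt in c("M+P", "P", "D+P")) {
    tr <- run_cohort(spec, trt)
    occ <- c(10000, 0, 0)
    for (t in 1:40) {
      occ <- as.numeric(occ %*% build_matrix(spec, trt, t))
      expect_equal(
        as.numeric(tr$occupancy[t + 1, spec$states]), occ,
        tolerance = 1e-10
      )
    }
  }
  # constant-matrix special case: occupancy is the matrix power
  spec_exp <- markov_spec("three_state",
                          weibull = list(shape = 1, rate = 0.08),
                          hr = c("A" = 1), pd_death_tp = 0.1,
                          n_cycles = 15)
  m <- build_matrix(spec_exp, "A", 1)
  mp <- diag(3)
  tr <- run_cohort(spec_exp, "A")
  for (t in 1:15) mp <- mp %*% m
  expect_equal(as.numeric(tr$occupancy[16, spec_exp$states]),
               as.numeric(c(10000, 0, 0) %*% mp), tolerance = 1e-9)
})

test_that("an immediately-fatal model empties the cohort in one cycle", {
  spec <- markov_spec("two_state", weibull = list(shape = 1, rate = 50),
                      hr = c("A" = 1), n_cycles = 3)
  tr <- run_cohort(spec, "A")
  expect_equal(tr$occupancy$Dead[2], 10000, tolerance = 1e-6)
  expect_equal(tr$occupancy$Alive[2], 0, tolerance = 1e-6)
})

test_that("a single-cycle progressive-disease month accrues UPD/12", {
  # hand-built trace: the whole cohort spends one undiscounted cycle in
  # the progressed state
  spec <- markov_spec("three_state", weibull = list(shape = 1, rate = 0.1),
                      hr = c("A" = 1), pd_death_tp = 0.05, n_cycles = 1)
  trace <- structure(list(
    occupancy = tibble::tibble(cycle = 0:1, StableDisease = c(0, 0),
                               ProgressiveDisease = c(10000, 10000),
                               Dead = c(0, 0)),
    entries = tibble::tibble(cycle = integer(), from = character(),
                             to = character(), count = numeric()),
    dead_entries = 0,
    std_tp = tibble::tibble(cycle = 1, stay = 0.945, pd = 0.05,
                            dead_other = 0.005),
    spec = spec, treatment = "A"
  ), class = "state_trace")
  u <- list(surviving = 0.770, pd = 0.538, other_causes = 0.564)
  out <- expected_cost_qaly(
    trace,
    costs = list(acquisition = 0, followup_monthly = 0,
                 followup_pd_fraction = 0.75, terminal = 0),
    utilities = u
  )
  expect_equal(out$qaly, 0.538 / 12)
  expect_equal(out$cost, 0)
})

test_that("discounted totals split additively over a partition of the cycles", {
  spec <- fixture_spec(n_cycles = 60)
  tr <- run_cohort(spec, "D+P")
  costs <- list(acquisition = 0, followup_monthly = 230,
                followup_pd_fraction = 0.75, terminal = 2500)
  u <- list(surviving = 0.770, pd = 0.538, other_causes = 0.564)
  full <- expected_cost_qaly(tr, costs, u)
  mask <- function(tr, keep) {
    tr$occupancy[!(tr$occupancy$cycle %in% keep), -1] <- 0
    tr$dead_entries[setdiff(1:60, keep)] <- 0
    tr
  }
  first <- expected_cost_qaly(mask(tr, 1:30), costs, u)
  second <- expected_cost_qaly(mask(tr, 31:60), costs, u)
  expect_equal(first$cost + second$cost, full$cost, tolerance = 1e-9)
  expect_equal(first$qaly + second$qaly, full$qaly, tolerance = 1e-9)
})

test_that("the PSA fast path equals the trace-based accounting exactly", {
  spec <- fixture_spec()
  costs <- list(acquisition = 7260, followup_monthly = 230,
                followup_pd_fraction = 0.72, terminal = 2500)
  u <- list(surviving = 0.770, pd = 0.538, other_causes = 0.564,
            alive = 0.538)
  for (trt in names(spec$hr)) {
    fast <- metacea:::cohort_cost_qaly(spec, trt, costs, u)
    slow <- expected_cost_qaly(run_cohort(spec, trt), costs, u)
    expect_identical(unname(fast["cost"]), slow$cost)
    expect_identical(unname(fast["qaly"]), slow$qaly)
  }
  spec2 <- fixture_spec("two_state")
  fast <- metacea:::cohort_cost_qaly(spec2, "P", costs, u)
  slow <- expected_cost_qaly(run_cohort(spec2, "P"), costs, u)
  expect_identical(unname(fast["cost"]), slow$cost)
  expect_identical(unname(fast["qaly"]), slow$qaly)
})
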