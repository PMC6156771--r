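make_psa <- function(cost, qaly) {
  trts <- colnames(cost)
  out <- purrr::map(seq_along(trts), function(k) {
    tibble::tibble(draw = seq_len(nrow(cost)), treatment = trts[k],
                   cost = cost[, k], qaly = qaly[, k])
  }) |> purrr::list_rbind()
  class(out) <- c("psa_result", class(out))
  attr(out, "settings") <- list(model = "synthetic",
                                n_draws = nrow(cost), seed = NA,
                                baseline = trts[1])
  out
}

test_that("the ICER is the ratio of mean increments", {
  set.seed(71)
  n <- 4000
  cost <- cbind(ref = rnorm(n, 11000, 2000),
                comp = rnorm(n, 11000, 2000) + rnorm(n, 4624, 500))
  qaly <- cbind(ref = pmax(rnorm(n, 0.81, 0.1), 0),
                comp = pmax(rnorm(n, 0.81, 0.1), 0))
  qaly[, "comp"] <- qaly[, "ref"] + 0.154
  psa <- make_psa(cost, qaly)
  res <- incremental_icer(psa, "ref", "comp")
  expect_equal(res$status, "icer")
  expect_equal(res$icer, res$delta_cost / res$delta_qaly)
  expect_equal(res$delta_qaly, 0.154, tolerance = 1e-9)
  # swapping arms negates the increments
  rev <- incremental_icer(psa, "comp", "ref")
  expect_equal(rev$delta_cost, -res$delta_cost)
  expect_equal(rev$delta_qaly, -res$delta_qaly)
})

test_that("dominance and undefined cases are labelled, not signed ratios", {
  cost <- cbind(ref = c(100, 100), comp = c(50, 50))
  qaly <- cbind(ref = c(1, 1), comp = c(1.2, 1.2))
  expect_equal(incremental_icer(make_psa(cost, qaly),
                                "ref", "comp")$status, "dominant")
  expect_equal(incremental_icer(make_psa(cost, qaly),
                                "comp", "ref")$status, "dominated")
  same <- make_psa(cbind(ref = c(1, 2), comp = c(1, 2)),
                   cbind(ref = c(1, 1), comp = c(1, 1)))
  res <- incremental_icer(same, "ref", "comp")
  expect_equal(res$status, "undefined")
  expect_true(is.na(res$icer))
  # equal cost, more QALYs: ICER 0 and dominant
  zero <- make_psa(cbind(ref = c(1, 2), comp = c(1, 2)),
                   cbind(ref = c(1, 1), comp = c(1.5, 1.5)))
  res0 <- incremental_icer(zero, "ref", "comp")
  expect_equal(res0$status, "dominant")
  expect_equal(res0$icer, 0)
})

test_that("net benefit is willingness-to-pay times QALY minus cost", {
  expect_equal(net_benefit(0, 0, 30000), 0)
  expect_equal(net_benefit(100, 0, 0), -100)
  expect_equal(round(net_benefit(15862, 0.967, 30000)), 13148)
  expect_error(net_benefit(1, 1, -5), "non-negative")
})

test_that("acceptability curves normalise and handle ties and degeneracy", {
  # one draw: indicator curves
  one <- make_psa(cbind(A = 10, B = 5), cbind(A = 1, B = 1))
  cv <- ceac(one, c(0, 10))
  expect_equal(cv$probability[cv$treatment == "B"], c(1, 1))
  expect_equal(cv$probability[cv$treatment == "A"], c(0, 0))
  # exact ties split the weight
  tied <- make_psa(cbind(A = c(5, 5), B = c(5, 5)),
                   cbind(A = c(1, 1), B = c(1, 1)))
  cvt <- ceac(tied, 20000)
  expect_equal(cvt$probability, c(0.5, 0.5))
  # probabilities sum to one at every threshold
  set.seed(72)
  n <- 500
  psa <- make_psa(
    cbind(A = rnorm(n, 10000, 3000), B = rnorm(n, 12000, 3000),
          C = rnorm(n, 9000, 3000)),
    cbind(A = abs(rnorm(n, 0.8, 0.2)), B = abs(rnorm(n, 0.95, 0.2)),
          C = abs(rnorm(n, 0.7, 0.2)))
  )
  cvs <- ceac(psa, seq(0, 50000, 5000))
  sums <- dplyr::summarise(dplyr::group_by(cvs, wtp),
                           s = sum(probability))
  expect_equal(sums$s, rep(1, nrow(sums)), tolerance = 1e-12)
  # empty grid: empty curves
  expect_equal(nrow(ceac(psa, numeric())), 0)
})

test_that("the CEAC winner need not maximise expected net benefit", {
  # A usually wins slightly but occasionally loses big: A tops the CEAC
  # while B tops the mean net benefit
  cost_a <- c(rep(0, 6), rep(200, 4))
  psa <- make_psa(cbind(A = cost_a, B = rep(0, 10)),
                  cbind(A = rep(1, 10), B = rep(0.9, 10)))
  w <- 10
  cv <- ceac(psa, w)
  top_ceac <- cv$treatment[which.max(cv$probability)]
  wide <- metacea:::psa_wide(psa, c("A", "B"))
  nb <- w * wide$qaly - wide$cost
  top_mean <- colnames(nb)[which.max(colMeans(nb))]
  expect_equal(top_ceac, "A")
  expect_equal(top_mean, "B")
})

test_that("per-person EVPI matches brute force and the normal closed form", {
  # point mass: no uncertainty, no value of information
  pm <- make_psa(cbind(A = rep(10, 5), B = rep(12, 5)),
                 cbind(A = rep(1, 5), B = rep(1, 5)))
  expect_equal(evpi_per_person(pm, 30000), 0)

  set.seed(73)
  n <- 1000
  psa <- make_psa(
    cbind(A = rnorm(n, 10000, 2000), B = rnorm(n, 10500, 2500),
          C = rnorm(n, 9500, 1500)),
    cbind(A = abs(rnorm(n, 0.8, 0.15)), B = abs(rnorm(n, 0.9, 0.2)),
          C = abs(rnorm(n, 0.75, 0.1)))
  )
  w <- 25000
  # brute force: two explicit loops over draws and treatments
  tab <- as.data.frame(psa)
  draws <- sort(unique(tab$draw))
  trts <- unique(tab$treatment)
  best_per_draw <- numeric(length(draws))
  mean_nb <- setNames(numeric(length(trts)), trts)
  for (k in seq_along(draws)) {
    nbs <- sapply(trts, function(tr) {
      row <- tab[tab$draw == draws[k] & tab$treatment == tr, ]
      w * row$qaly - row$cost
    })
    best_per_draw[k] <- max(nbs)
  }
  for (tr in trts) {
    rows <- tab[tab$treatment == tr, ]
    mean_nb[tr] <- mean(w * rows$qaly - rows$cost)
  }
  oracle <- mean(best_per_draw) - max(mean_nb)
  expect_equal(evpi_per_person(psa, w), oracle)

  # centred-normal difference: EVPI = sigma / sqrt(2*pi)
  set.seed(74)
  n <- 40000
  psa2 <- make_psa(cbind(A = rep(0, n), B = rnorm(n, 0, 100)),
                   cbind(A = rep(1, n), B = rep(1, n)))
  expect_equal(evpi_per_person(psa2, 0), 100 / sqrt(2 * pi),
               tolerance = 0.05)
  # monotone in the option set
  expect_gte(evpi_per_person(psa, w),
             evpi_per_person(dplyr::filter(psa, treatment != "C"), w))
})

test_that("population EVPI applies the discounted incidence multiplier", {
  mult <- population_evpi(1, horizon = 12, incidence = 9000,
                          rate = 0.035)
  expect_equal(mult / 9000, 10.0017, tolerance = 1e-4)
  expect_equal(population_evpi(2.5, horizon = 12, incidence = 9000,
                               rate = 0.035), 2.5 * mult)
  expect_equal(population_evpi(1, horizon = 10, incidence = 500,
                               rate = 0), 5000)
  # discounting the first year scales the whole sum by 1/(1+r)
  expect_equal(
    population_evpi(1, discount_first_year = TRUE) * 1.035,
    population_evpi(1, discount_first_year = FALSE)
  )
})
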