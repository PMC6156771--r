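test_that("Cox estimate matches large-sample rate-ratio oracle", {
  # exponential arms with rates 0.10 vs 0.07: true log HR = log(0.7)
  ipd <- dplyr::bind_rows(
    simulate_ipd(8000, shape = 1, rate = 0.10, hr = 1, seed = 23)[
      1:8000, ],
    simulate_ipd(8000, shape = 1, rate = 0.07, hr = 1, seed = 24) |>
      dplyr::filter(arm == "ref") |>
      dplyr::mutate(arm = "comp2")
  )
  fit <- fit_cox_loghr(ipd, "ref", "comp2")
  expect_lt(abs(fit$loghr - log(0.7)), 0.05)
  expect_gt(fit$n_events, 0)
})

test_that("Cox fit agrees with an independent partial-likelihood Newton solver", {
  set.seed(31)
  for (i in 1:50) {
    n <- sample(30:100, 1)
    ipd <- simulate_ipd(n, shape = runif(1, 0.8, 1.5),
                        rate = runif(1, 0.02, 0.1),
                        hr = exp(runif(1, -0.8, 0.8)),
                        censor_time = runif(1, 12, 60),
                        seed = 3000 + i)
    if (sum(ipd$event) < 5) next
    fit <- fit_cox_loghr(ipd, "ref", "comp")
    oracle <- cox_newton(ipd$time_months, ipd$event,
                         as.integer(ipd$arm == "comp"))
    expect_equal(fit$loghr, oracle$loghr, tolerance = 1e-4)
    expect_equal(fit$se, oracle$se, tolerance = 1e-4)
  }
})

test_that("Cox fit validates its inputs", {
  ipd <- simulate_ipd(50, shape = 1, rate = 0.05, seed = 1)
  expect_error(fit_cox_loghr(ipd, "ref", "nope"), "present")
  censored <- dplyr::mutate(ipd, event = 0L)
  expect_error(fit_cox_loghr(censored, "ref", "comp"), "no events")
})

test_that("Weibull MLE recovers generating parameters", {
  # exponential special case
  ipd <- simulate_ipd(5000, shape = 1, rate = 0.05, seed = 41)
  fit <- fit_weibull_mle(ipd, arm = "ref")
  expect_lt(abs(fit$shape - 1), 0.05)
  expect_lt(abs(fit$rate - 0.05), 0.005)

  # censored case: both parameters within 3 asymptotic SEs
  ipd <- simulate_ipd(5000, shape = 1.2, rate = 0.02,
                      censor_time = 40, seed = 42)
  expect_lt(mean(ipd$event), 0.95)  # real censoring present
  fit <- fit_weibull_mle(ipd, arm = "ref")
  se_log <- sqrt(diag(fit$vcov_log))
  expect_lt(abs(log(fit$shape) - log(1.2)), 3 * se_log["log_shape"])
  expect_lt(abs(log(fit$rate) - log(0.02)), 3 * se_log["log_rate"])
})

test_that("Weibull MLE matches an independent proportional-hazards fit", {
  skip_if_not_installed("flexsurv")
  ipd <- simulate_ipd(800, shape = 1.3, rate = 0.03, censor_time = 30,
                      seed = 43)
  fit <- fit_weibull_mle(ipd, arm = "ref")
  ref <- ipd[ipd$arm == "ref", ]
  alt <- flexsurv::flexsurvreg(
    survival::Surv(time_months, event) ~ 1, data = ref,
    dist = "weibullPH"
  )
  expect_equal(fit$shape, unname(alt$res["shape", "est"]),
               tolerance = 1e-3)
  expect_equal(fit$rate, unname(alt$res["scale", "est"]),
               tolerance = 1e-3)
})

test_that("Weibull MLE rejects degenerate inputs", {
  ipd <- simulate_ipd(100, shape = 1, rate = 0.01, censor_time = 0.5,
                      seed = 44)
  ipd$event <- 0L
  expect_error(fit_weibull_mle(ipd), "2 events")
  bad <- tibble::tibble(study_id = "S", arm = "ref",
                        time_months = c(0, 0, 1, 2),
                        event = c(1L, 1L, 1L, 1L))
  expect_error(fit_weibull_mle(bad), "positive")
})

test_that("time rescaling leaves the shape invariant and rescales the scale", {
  ipd <- simulate_ipd(2000, shape = 1.2, rate = 0.03, censor_time = 40,
                      seed = 45)
  fit1 <- fit_weibull_mle(ipd, arm = "ref")
  scaled <- dplyr::mutate(ipd, time_months = time_months * 2.5)
  fit2 <- fit_weibull_mle(scaled, arm = "ref")
  expect_equal(fit2$shape, fit1$shape, tolerance = 1e-6)
  # lambda^(-1/gamma) is the natural time scale: multiplies by c
  expect_equal(fit2$rate^(-1 / fit2$shape),
               2.5 * fit1$rate^(-1 / fit1$shape), tolerance = 1e-6)
})

test_that("weibull_mean matches closed form and numerical integration", {
  expect_equal(weibull_mean(1, 0.05), 20)
  expect_equal(weibull_mean(1, 0.1), 10)
  expect_equal(round(weibull_mean(2, 0.01), 4), 8.8623)
  for (par in list(c(0.9, 0.08), c(1.4, 0.02), c(2.2, 0.005))) {
    num <- integrate(function(t) exp(-par[2] * t^par[1]), 0, Inf,
                     rel.tol = 1e-10)$value
    expect_equal(weibull_mean(par[1], par[2]), num, tolerance = 1e-6)
  }
})
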