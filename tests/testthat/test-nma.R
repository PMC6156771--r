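two_edge_network <- function() {
  # M+P vs P pooled PFS edge and D+P vs M+P predicted PFS edge, on the
  # log HR scale with interval-derived SEs
  e1 <- hr_ci_to_log(0.641, 0.532, 0.772)
  e2 <- hr_ci_to_log(0.619, 0.393, 0.924)
  study_table(
    study_id = c("pooled-MP-P", "predicted-DP-MP"),
    ref = c("P", "M+P"), comp = c("M+P", "D+P"),
    loghr_pfs = c(e1$loghr, e2$loghr), se_pfs = c(e1$se, e2$se),
    loghr_os = NA, se_os = NA
  )
}

test_that("a single-edge network reproduces the pairwise result", {
  s <- study_table(
    study_id = c("A", "B"), ref = "P", comp = "M+P",
    loghr_os = c(-0.2, -0.05), se_os = c(0.15, 0.2)
  )
  nma <- fit_nma(s, "os", "fixed", baseline = "P",
                 mcmc = quick_mcmc(61, 12000, 3000))
  ma <- fit_ma_common(tibble::tibble(y = s$loghr_os, se = s$se_os),
                      quick_mcmc(62, 12000, 3000))
  ct <- nma$contrasts[nma$contrasts$comp == "M+P" &
                        nma$contrasts$ref == "P", ]
  pl <- ma$summary[ma$summary$param == "theta", ]
  expect_lt(abs(ct$mean - pl$mean), 0.01)
  expect_lt(abs(ct$sd - pl$sd), 0.01)
})

test_that("fixed-effect contrasts compose along a tree network", {
  nma <- fit_nma(two_edge_network(), "pfs", "fixed", baseline = "P",
                 mcmc = quick_mcmc(63, 20000, 5000))
  indirect <- nma$contrasts[nma$contrasts$comp == "D+P" &
                              nma$contrasts$ref == "P", ]
  # log-scale sum: 0.641 * 0.619 = 0.397
  expect_equal(indirect$hr_mean, 0.641 * 0.619, tolerance = 0.01)
  # edge contrasts are recovered
  direct <- nma$contrasts[nma$contrasts$comp == "M+P" &
                            nma$contrasts$ref == "P", ]
  expect_equal(direct$hr_mean, 0.641, tolerance = 0.01)
})

test_that("contrasts are antisymmetric and consistent per draw", {
  s <- simulate_study_set(n_studies = 3, seed = 64)
  s$ref <- c("P", "P", "M+P")
  s$comp <- c("M+P", "D+P", "D+P")
  nma <- fit_nma(s, "os", "fixed", baseline = "P",
                 mcmc = quick_mcmc(64, 4000, 1000))
  dab <- contrast_draws(nma, "M+P", "P")
  dbc <- contrast_draws(nma, "D+P", "M+P")
  dca <- contrast_draws(nma, "P", "D+P")
  expect_equal(dab + dbc + dca, rep(0, length(dab)))
  expect_equal(contrast_draws(nma, "P", "M+P"), -dab)
  ct <- nma$contrasts
  ab <- ct[ct$comp == "M+P" & ct$ref == "P", ]
  ba <- ct[ct$comp == "P" & ct$ref == "M+P", ]
  expect_equal(ab$mean, -ba$mean)
})

test_that("disconnected networks are refused with the components named", {
  s <- study_table(
    study_id = c("A", "B"), ref = c("P", "X"), comp = c("M+P", "Y"),
    loghr_os = c(-0.1, -0.2), se_os = c(0.1, 0.1)
  )
  expect_error(fit_nma(s, "os", "fixed", baseline = "P"),
               "disconnected.*X|disconnected.*Y")
})

test_that("random-effects variant reports a heterogeneity SD", {
  s <- simulate_study_set(n_studies = 6, tau_os = 0.3, seed = 65)
  nma <- suppressWarnings(
    fit_nma(s, "os", "random", baseline = "P",
            mcmc = quick_mcmc(65, 6000, 2000)))
  expect_true("tau" %in% nma$diagnostics$param)
  expect_true(all(nma$draws$tau >= 0))
})

test_that("predicted estimates are substituted and flagged for the NMA", {
  fx <- hta_fixture()
  fit <- suppressWarnings(
    fit_brma(fx$studies, mcmc = quick_mcmc(66, 6000, 2000)))
  aug <- augment_with_predictions(fx$studies, fit)
  tax <- aug[aug$study_id == "TAX 327", ]
  expect_false(is.na(tax$loghr_pfs))
  expect_true(tax$predicted_pfs)
  expect_false(any(aug$predicted_os))
  expect_equal(tax$loghr_pfs, fit$predictions$median)
  # interval-derived SE, not the (tail-dominated) posterior SD
  expect_equal(tax$se_pfs,
               (fit$predictions$q97.5 - fit$predictions$q2.5) /
                 (2 * 1.959964))
  nma <- fit_nma(aug, "pfs", "fixed", baseline = "P",
                 mcmc = quick_mcmc(67, 4000, 1000))
  expect_equal(sort(nma$treatments), sort(c("P", "M+P", "D+P")))
})
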