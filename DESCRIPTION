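Package: metacea
Title: Bayesian Evidence Synthesis and Markov Cost-Effectiveness Modelling
    for Correlated Survival Outcomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for multiparameter evidence synthesis feeding a
    probabilistic cost-effectiveness decision model. Implements Bayesian
    common-effect and random-effects meta-analysis, bivariate random-effects
    meta-analysis (BRMA) of correlated overall-survival and
    progression-free-survival log hazard ratios with MCMC prediction of
    unreported study-level treatment effects, and contrast-based network
    meta-analysis, all on the log hazard ratio scale. Posterior draws
    propagate into 2-state and 3-state Markov cohort models with
    time-dependent Weibull transition probabilities, cost and utility
    accrual, and discounting, yielding incremental cost-effectiveness
    ratios, net monetary benefit, cost-effectiveness acceptability curves,
    and population expected value of perfect information. Includes a
    synthetic-data module for study-level bivariate evidence and Weibull
    survival data with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    coda,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rjags,
    rlang,
    stats,
    survival,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    flexsurv,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
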