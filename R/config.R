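#' Analysis configuration for the full pipeline
#'
#' Bundles prior settings, MCMC run lengths, Markov and PSA settings,
#' willingness-to-pay grid and EVPI settings. Defaults are the case-study
#' settings: 30,000 iterations / 15,000 burn-in for the evidence
#' synthesis, 180 monthly cycles with a 10,000-patient cohort, 3.5%/year
#' discounting from cycle 13, and a 12-year, 9,000-patients/year EVPI
#' population.
#'
#' @param priors A [brma_priors()].
#' @param mcmc An [mcmc_control()] for the evidence-synthesis stages.
#' @param psa_draws Number of PSA iterations per decision model.
#' @param ma_ref,ma_comp Contrast pooled in the pairwise meta-analysis
#'   stage (`comp` versus `ref`).
#' @param icer_ref,icer_comp Treatments compared in the incremental
#'   analysis.
#' @param nb_wtp Thresholds at which net-benefit and EVPI tables are
#'   reported.
#' @param wtp_grid Thresholds for the acceptability curves; may be empty.
#' @param evpi List with `horizon_years`, `incidence`, `discount_rate`.
#' @param ma_variant `"fixed"` or `"random"`: which pooled posterior feeds
#'   the decision models.
#' @param seed Master seed; stage seeds are derived from it.
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(priors = brma_priors(),
                            mcmc = mcmc_control(),
                            psa_draws = 2000,
                            ma_ref = "P", ma_comp = "M+P",
                            icer_ref = "M+P", icer_comp = "D+P",
                            nb_wtp = c(20000, 30000),
                            wtp_grid = seq(0, 50000, by = 2500),
                            evpi = list(horizon_years = 12,
                                        incidence = 9000,
                                        discount_rate = 0.035),
                            ma_variant = c("fixed", "random"),
                            seed = 1) {
  ma_variant <- match.arg(ma_variant)
  stopifnot(inherits(priors, "brma_priors"), inherits(mcmc, "mcmc_control"),
            psa_draws >= 1, all(nb_wtp >= 0), all(wtp_grid >= 0),
            evpi$horizon_years >= 1, evpi$incidence >= 0,
            evpi$discount_rate >= 0, evpi$discount_rate < 1)
  structure(
    list(priors = priors, mcmc = mcmc, psa_draws = as.integer(psa_draws),
         ma_ref = ma_ref, ma_comp = ma_comp,
         icer_ref = icer_ref, icer_comp = icer_comp,
         nb_wtp = nb_wtp, wtp_grid = wtp_grid, evpi = evpi,
         ma_variant = ma_variant, seed = as.integer(seed)),
    class = "analysis_config"
  )
}

#' Read an analysis configuration from YAML or JSON
#'
#' Recognised keys mirror the arguments of [analysis_config()], with
#' `mcmc: {iterations, burnin, chains, seed}` and nested `priors`,
#' `evpi` blocks; absent keys keep their defaults.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return An `analysis_config`.
#' @export
read_analysis_config <- function(path) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  args <- list()
  if (!is.null(raw$mcmc)) {
    args$mcmc <- mcmc_control(
      n_iter = raw$mcmc$iterations %||% 30000,
      n_burnin = raw$mcmc$burnin %||% 15000,
      n_chains = raw$mcmc$chains %||% 2,
      seed = raw$mcmc$seed %||% 1
    )
    args$seed <- as.integer(raw$mcmc$seed %||% 1)
  }
  if (!is.null(raw$priors)) {
    args$priors <- do.call(brma_priors, raw$priors)
  }
  for (key in c("psa_draws", "ma_ref", "ma_comp", "icer_ref", "icer_comp",
                "nb_wtp", "wtp_grid", "evpi", "ma_variant", "seed")) {
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  }
  do.call(analysis_config, args)
}
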