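#' Incremental cost-effectiveness analysis of two treatments
#'
#' Computes per-draw incremental cost and QALY of `comp` versus `ref`,
#' their means and SDs over the PSA distribution, and the incremental
#' cost-effectiveness ratio defined as the ratio of means (mean incremental
#' cost over mean incremental QALY). Dominance is labelled instead of
#' reporting a signed ratio: `dominant` (cheaper and more effective),
#' `dominated` (costlier and less effective), otherwise the ICER.
#'
#' @param psa A `psa_result` from [run_psa()] (or any tibble with `draw`,
#'   `treatment`, `cost`, `qaly`).
#' @param ref,comp Treatment codes.
#' @return A one-row tibble: `comp`, `ref`, `delta_cost`, `delta_cost_se`,
#'   `delta_qaly`, `delta_qaly_se`, `icer`, `status`.
#' @export
incremental_icer <- function(psa, ref, comp) {
  wide <- psa_wide(psa, c(ref, comp))
  dc <- wide$cost[, comp] - wide$cost[, ref]
  dq <- wide$qaly[, comp] - wide$qaly[, ref]
  mdc <- mean(dc)
  mdq <- mean(dq)
  status <- "icer"
  icer <- NA_real_
  if (mdq == 0) {
    status <- "undefined"
  } else if (mdc <= 0 && mdq > 0) {
    status <- "dominant"
    icer <- if (mdc == 0) 0 else NA_real_
  } else if (mdc >= 0 && mdq < 0) {
    status <- "dominated"
  } else {
    icer <- mdc / mdq
  }
  tibble(
    comp = comp, ref = ref,
    delta_cost = mdc, delta_cost_se = sd(dc),
    delta_qaly = mdq, delta_qaly_se = sd(dq),
    icer = icer, status = status
  )
}

#' Net monetary benefit
#'
#' `wtp * qaly - cost`, in GBP.
#'
#' @param cost,qaly Cost (GBP) and QALYs (vectorised).
#' @param wtp Willingness-to-pay threshold (GBP per QALY, >= 0).
#' @return Net monetary benefit in GBP.
#' @examples
#' net_benefit(15862, 0.967, 30000)
#' @export
net_benefit <- function(cost, qaly, wtp) {
  if (any(wtp < 0)) abort("`wtp` must be non-negative.")
  wtp * qaly - cost
}

#' Cost-effectiveness acceptability curves
#'
#' At each willingness-to-pay threshold, the probability that a treatment
#' is cost-effective is the fraction of PSA draws in which it attains the
#' strictly greatest net benefit; exact ties split the draw's weight
#' equally among the tied treatments, so probabilities sum to one at every
#' threshold.
#'
#' @param psa A `psa_result`.
#' @param wtp_grid Numeric vector of thresholds (may be empty).
#' @return A tibble of class `ceac` with columns `wtp`, `treatment`,
#'   `probability`.
#' @export
ceac <- function(psa, wtp_grid) {
  trts <- unique(as_tibble(psa)$treatment)
  if (length(trts) < 2) abort("CEAC needs at least 2 treatments.")
  if (!length(wtp_grid)) {
    out <- tibble(wtp = double(), treatment = character(),
                  probability = double())
    class(out) <- c("ceac", class(out))
    return(out)
  }
  wide <- psa_wide(psa, trts)
  out <- purrr::map(wtp_grid, function(w) {
    nb <- w * wide$qaly - wide$cost
    is_max <- nb == row_maxs(nb)
    wgt <- is_max / rowSums(is_max)
    tibble(wtp = w, treatment = trts,
           probability = unname(colMeans(wgt)[trts]))
  }) |> purrr::list_rbind()
  class(out) <- c("ceac", class(out))
  out
}

# rowMaxs without a matrixStats dependency
row_maxs <- function(m) {
  do.call(pmax, as.data.frame(m))
}

#' Per-person expected value of perfect information
#'
#' `EVPI = E_draw[max_t NB_t] - max_t E_draw[NB_t]` at the given
#' willingness-to-pay: the expected gain of deciding with perfect
#' knowledge of the parameters over deciding on current expectations.
#' Always non-negative; zero only when one treatment maximizes net benefit
#' in every draw.
#'
#' @param psa A `psa_result`.
#' @param wtp Willingness-to-pay threshold.
#' @return EVPI per person, GBP.
#' @export
evpi_per_person <- function(psa, wtp) {
  trts <- unique(as_tibble(psa)$treatment)
  if (length(trts) < 2) abort("EVPI needs at least 2 treatments.")
  wide <- psa_wide(psa, trts)
  nb <- wtp * wide$qaly - wide$cost
  mean(row_maxs(nb)) - max(colMeans(nb))
}

#' Scale per-person EVPI to the incident population
#'
#' Multiplies the per-person EVPI by the discounted number of patients the
#' decision affects: `incidence` new patients per year over `horizon`
#' years, discounted annually. By default the first year is undiscounted
#' (`sum_{t=1..horizon} incidence * (1 + rate)^-(t-1)`);
#' `discount_first_year = TRUE` discounts every year.
#'
#' @param evpi_pp Per-person EVPI (GBP).
#' @param horizon Decision-relevance horizon in years.
#' @param incidence Incident patients per year.
#' @param rate Annual discount rate.
#' @param discount_first_year Discount year 1 as well.
#' @return Population EVPI, GBP.
#' @examples
#' population_evpi(1, horizon = 12, incidence = 9000, rate = 0.035)
#' @export
population_evpi <- function(evpi_pp, horizon = 12, incidence = 9000,
                            rate = 0.035, discount_first_year = FALSE) {
  stopifnot(evpi_pp >= 0 || is.na(evpi_pp), horizon >= 1, incidence >= 0,
            rate >= 0)
  expo <- seq_len(horizon) - if (discount_first_year) 0 else 1
  evpi_pp * sum(incidence * (1 + rate)^(-expo))
}

# Per-draw cost and QALY matrices (draws x treatments).
psa_wide <- function(psa, trts) {
  psa <- as_tibble(psa)
  missing_trt <- setdiff(trts, unique(psa$treatment))
  if (length(missing_trt)) {
    abort(paste0("Treatment(s) not in the PSA: ",
                 paste(missing_trt, collapse = ", ")))
  }
  psa <- psa[psa$treatment %in% trts, ]
  counts <- table(psa$treatment)
  if (length(unique(counts)) != 1) {
    abort("All treatments must share the same number of PSA draws.")
  }
  cost <- tidyr::pivot_wider(psa[, c("draw", "treatment", "cost")],
                             names_from = "treatment",
                             values_from = "cost")
  qaly <- tidyr::pivot_wider(psa[, c("draw", "treatment", "qaly")],
                             names_from = "treatment",
                             values_from = "qaly")
  list(cost = as.matrix(cost[, trts]), qaly = as.matrix(qaly[, trts]))
}
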