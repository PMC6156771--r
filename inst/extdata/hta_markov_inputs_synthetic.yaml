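# Synthetic decision-model inputs for the mHRPC docetaxel case study.
#
# Provenance, field by field:
#   * utilities and the other-cause death transition probability are the
#     published values (EQ-5D 0.770 +/- 0.015 surviving, 0.538 +/- 0.077
#     progressive disease, 0.564 +/- 0.067 other-cause deaths; other-cause
#     monthly tp 0.005 applied with no uncertainty).
#   * discounting (3.5%/year from cycle 13), cycle structure (180 monthly
#     cycles, cohort 10,000) and EVPI settings (12-year horizon, 9,000
#     incident patients/year, 3.5%) are the published analysis settings.
#   * Weibull parameters and costs are SYNTHETIC stand-ins: the originals
#     live in an HTA report that is not distributed with this package.
#     The OS Weibull is anchored to the published 18-month median overall
#     survival and the PFS Weibull to the published 6-month median PFS
#     (both on the baseline mitoxantrone+prednisolone arm); shapes and
#     log-scale uncertainty are typical of trial-sized survival fits.
#     Costs are round numbers of HTA-report magnitude (docetaxel regimen
#     acquisition ~7k GBP, mitoxantrone ~3k GBP). Treat every number in
#     the `weibull` and `costs` blocks as approximate.
treatments:
  codes: [P, M+P, D+P]
  baseline: M+P
weibull:
  # S(t) = exp(-rate * t^shape), t in months
  os:
    shape: 1.25
    rate: 0.018695
    sd_log_shape: 0.03
    sd_log_rate: 0.08
    corr_log: -0.5
  pfs:
    shape: 1.10
    rate: 0.096574
    sd_log_shape: 0.04
    sd_log_rate: 0.10
    corr_log: -0.5
transition:
  other_cause_tp: 0.005
  p_pc_death: 0.93
  m_other_months: 12
utilities:
  surviving: {mean: 0.770, se: 0.015}
  pd: {mean: 0.538, se: 0.077}
  other_causes: {mean: 0.564, se: 0.067}
  alive_two_state: {mean: 0.538, se: 0.077}
costs:
  acquisition:
    P: 490
    M+P: 2870
    D+P: 7260
  followup_monthly: {mean: 230, se: 35}
  followup_pd_fraction: [0.70, 0.80]
  terminal: {mean: 2500, se: 400}
markov:
  cycles: 180
  cycle_months: 1
  cohort: 10000
  discount_rate: 0.035
  discount_start_cycle: 13
evpi:
  horizon_years: 12
  incidence: 9000
  discount_rate: 0.035
wtp_grid: [0, 2500, 5000, 7500, 10000, 12500, 15000, 17500, 20000, 22500,
           25000, 27500, 30000, 32500, 35000, 37500, 40000, 42500, 45000,
           47500, 50000]
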