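---
title: "Bivariate evidence synthesis and Markov cost-effectiveness modelling"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bivariate evidence synthesis and Markov cost-effectiveness modelling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE, collapse = TRUE, comment = "#>")
```

`metacea` implements a multiparameter evidence-synthesis pipeline for
health-technology assessment: study-level treatment effects on two
correlated survival outcomes — overall survival (OS) and progression-free
survival (PFS), both on the log hazard ratio scale — are synthesised
jointly so that an effect *unreported* by a trial can be predicted and
used to populate a more detailed decision model than the reported data
alone would allow. The motivating case study is docetaxel plus
prednisolone (D+P) for metastatic hormone-refractory prostate cancer,
where the pivotal trial reported OS but not PFS: predicting the missing
PFS effect upgrades a 2-state (alive/dead) Markov cost-effectiveness
model to a 3-state model (stable disease / progressive disease / dead).

This vignette is the package's account of the statistical models, their
assumptions, the numerical choices, and what the synthetic-data-based
test suite does and does not establish.

## The bivariate random-effects meta-analysis (BRMA)

Each study $i$ contributes estimates $(Y_{OS,i}, Y_{PFS,i})$ of the true
study-level effects $(\mu_{OS,i}, \mu_{PFS,i})$, with known standard
errors. The within-study level assumes the two estimates are bivariate
normal with correlation $\rho_{w,i}$; the between-study level assumes the
true effects are bivariate normal across studies. `fit_brma()` uses the
product-normal factorization of the between-study model:

$$
\mu_{OS,i} \sim N(\eta_{OS}, \tau_{OS}^2), \qquad
\mu_{PFS,i} \mid \mu_{OS,i} \sim
  N\!\big(\lambda_0 + \lambda_1(\mu_{OS,i} - \eta_{OS}),\ \psi^2\big),
$$

with slope $\lambda_1 = \rho_b \tau_{PFS}/\tau_{OS}$ and conditional
variance $\psi^2 = \tau_{PFS}^2 (1-\rho_b^2)$, where $\rho_b$ is the
between-study correlation and $\tau_{OS}, \tau_{PFS}$ the heterogeneity
SDs. The pooled hazard ratios are $e^{\eta_{OS}}$ and $e^{\lambda_0}$.
The conditional mean is centred at $\eta_{OS}$, which makes $\lambda_0$
the marginal pooled PFS effect.

Priors follow the vague evidence-synthesis convention: $N(0, 10^3)$
(variance $10^3$, SD $\approx 31.6$) on $\eta_{OS}$ and $\lambda_0$,
half-normal with variance $10^3$ on the heterogeneity SDs, and
$U(-1, 1)$ on $\rho_b$ and each $\rho_{w,i}$. The within-study
correlations are only weakly identified from aggregate data; they can be
pinned to an externally informed value with
`brma_priors(rho_w_fixed = ...)`.

**Prediction of a missing effect.** A study with a missing PFS estimate
still contributes its OS estimate. Its unobserved $Y_{PFS,i}$ is a
missing-data node sampled directly in the MCMC: the true effect comes
from the conditional between-study regression, and the within-study
standard error from an *exchangeable variance* model — the observed
study log-variances $\log \sigma^2_{PFS,i}$ are modelled as exchangeable
normal, and the missing study's log-variance is drawn from that
distribution. The hyperpriors of this model are a design choice the
literature leaves open: `metacea` uses a vague normal on the mean and
$U(0, 2)$ on the SD of the log-variances. The upper bound matters: an
SD of 2 already allows study SEs an order of magnitude apart; raising
the bound to 5 mostly widens the extreme tails of the predictive
distribution without moving its central 95% interval, which users can
check by refitting with `brma_priors(logvar_sd_upper = 5)`.

With only a handful of studies the half-normal (variance $10^3$)
heterogeneity priors are effectively flat, and the marginal posterior of
$\tau_{PFS}$ — hence of the predictive distribution — has polynomially
heavy tails. The posterior *median* and central interval of the
predicted effect are stable; the posterior SD is tail-dominated and
should not be used as a summary. Two downstream choices follow:

* `augment_with_predictions()` substitutes the predicted **median** with
  a standard error equal to the central 95% interval width divided by
  $2 \times 1.959964$, since the network meta-analysis likelihood treats
  the estimate as normal;
* `run_psa()` truncates treatment-effect draws to hazard ratios in
  $[1/10, 10]$ and says so with a counted warning. Effects beyond
  10-fold have no clinical meaning and would push monthly transition
  probabilities past feasibility, which the Markov engine treats as an
  error rather than clipping silently.

Convergence is monitored with split-chain $\hat R$ (threshold 1.05) and
effective sample sizes on all scalar parameters; a failing node flags
the fit (`converged = FALSE` plus a warning), never silently. MCMC run
lengths default to 30,000 iterations per chain with 15,000 burn-in on 2
chains, the case study's settings; all chains are seeded
deterministically from one integer seed.

## Pairwise and network meta-analysis

`fit_ma_common()` is the common-effect normal model (vague normal prior
on the pooled effect); its posterior agrees with the closed-form
inverse-variance estimate up to Monte Carlo error, which the test suite
checks against an independent oracle. `fit_ma_random()` is the
normal–normal hierarchical model with a half-normal prior on the
between-study SD and also returns the new-study predictive distribution.

`fit_nma()` is a contrast-based normal NMA on log hazard ratios with
basic parameters relative to a declared baseline, in fixed- and
random-effects variants (common heterogeneity SD, half-normal prior).
Indirect contrasts are sums of basic parameters, so on a tree network
the fixed-effect indirect hazard ratio is the product of the edge hazard
ratios: composing the case study's pooled M+P vs P PFS edge (0.641) with
the predicted D+P vs M+P edge (0.619) gives 0.397, which
`scripts/acceptance.R` recomputes end to end. Contrast antisymmetry and
the three-way consistency identity hold draw by draw and are tested.

## Survival inputs

Hazard ratios from individual patient data use `fit_cox_loghr()`
(Cox partial likelihood, Breslow ties by default, Efron behind a flag).
Parametric survival uses the Weibull in the
$S(t) = \exp(-\lambda t^\gamma)$ parameterization throughout, because
the transition-probability formula below depends on it.
`fit_weibull_mle()` maximizes the right-censored likelihood on
$(\log\lambda, \log\gamma)$ with an analytic gradient and returns the
asymptotic covariance on that scale for PSA sampling. The mean survival
time is $\Gamma(1 + 1/\gamma)\,\lambda^{-1/\gamma}$ (`weibull_mean()`).

## The Markov cohort models

Both decision models run 180 monthly cycles (a 15-year horizon) on a
cohort of 10,000, with no half-cycle correction (end-of-cycle accrual; a
correction is deliberately not applied, matching the reported model
structure).

* **2-state** (Alive/Dead): the alive-to-dead probability in cycle $t$
  comes from the baseline-treatment OS Weibull,
  $tp(t) = 1 - S(t)/S(t-1) = 1 - e^{\lambda (t-1)^\gamma - \lambda t^\gamma}$,
  scaled per treatment by its OS hazard ratio via
  $1-(1-tp)^{HR}$ (proportional hazards on the cycle survival
  fraction).
* **3-state** (StableDisease/ProgressiveDisease/Dead): the
  stable-to-progressed probability comes from the PFS Weibull scaled by
  the PFS hazard ratio; a fixed other-cause death probability of 0.005
  per cycle leaves the stable state with no uncertainty; and the
  progressed-to-dead probability is constant in time, identified from a
  mean-survival decomposition: mean OS equals the disease-death
  proportion times (mean PFS + mean progressive-disease duration
  $d_{PD}$) plus the other-cause proportion times its mean survival;
  `solve_pd_death_tp()` solves for $d_{PD}$ and returns
  $1 - e^{-1/d_{PD}}$, erroring (with the implied negative duration) if
  the decomposition is infeasible. Whether the original analysis held
  this probability constant in time is not derivable from the published
  text; the constant-rate solver is this package's declared
  interpretation.

Transition rows are built directly from these probabilities and never
renormalized; a row that would go negative is an error, because it
signals a mis-specified Weibull or hazard ratio. The engine's
cumulative-product implementation is tested against explicit
transition-matrix powers (exact) and a 100,000-person multinomial
microsimulation (within 3 binomial SEs).

**Costs** have three components: a one-off acquisition/administration
cost per treatment (charged undiscounted at entry), a monthly follow-up
cost, and a one-off terminal-care cost charged on each entry to Dead.
In the 3-state model the follow-up cost is split between the states: the
progressed state receives a fraction $f \sim U(0.70, 0.80)$ per PSA
iteration (the reported range for post-progression chemotherapy and
hospitalization costs, with no point value to anchor on), the stable
state $1-f$.

**Utilities** (EQ-5D): the 2-state alive state uses $0.538 \pm 0.077$,
the value measured in patients' last year of life. The 3-state model
keeps 0.538 for the progressive state and gives the stable state the
transition-probability-weighted mixture
$U_{StD}(t) = tp_{stay}(t)\,0.770 + tp_{progress}(t)\,0.538 +
0.005 \times 0.564$, so stable patients' utility reflects where they are
headed that cycle. QALYs accrue as occupancy-weighted utility times
1/12 year per cycle.

**Discounting** is 3.5% per year in annual steps from cycle 13: the
factor is 1 for the first 12 cycles and $(1.035)^{-\lfloor (t-1)/12
\rfloor}$ after. Continuous monthly compounding is a defensible
alternative the source text does not disambiguate; annual steps are the
package's choice and are pinned by unit tests (factors 1, 0.966184,
0.933511 at cycles 12, 13, 25).

## Probabilistic sensitivity analysis and decision metrics

`run_psa()` propagates uncertainty per draw: Weibull parameters from a
bivariate normal on $(\log\lambda, \log\gamma)$ with the stored
covariance; utilities from normals truncated to $[0,1]$ by inverse-CDF
sampling; costs with stated uncertainty from moment-matched gamma
distributions; the follow-up split from $U(0.70, 0.80)$; and treatment
effects directly from the posterior draws of the synthesis stage — so
the predicted missing PFS effect enters the 3-state model as a full
posterior distribution, not a summary. In the 3-state model the
progressed-to-dead probability is re-solved per draw from the drawn OS
and PFS Weibull means, inheriting their uncertainty; draws whose OS mean
falls at or below the PFS mean (a sampling artifact of independent
log-normal draws) are kept feasible by flooring the implied
progressive-disease duration at about half a month.

From the per-draw, per-treatment discounted costs and QALYs:

* `incremental_icer()`: the ICER is the **ratio of means** (mean
  incremental cost over mean incremental QALY), with dominance labelled
  rather than reported as a signed ratio;
* `net_benefit()`: $\lambda\,\text{QALY} - \text{cost}$;
* `ceac()`: at each willingness-to-pay, the probability a treatment has
  the strictly greatest net benefit, exact ties splitting the draw's
  weight equally — so the curves sum to one, and the CEAC winner need
  not be the expected-net-benefit winner (a regression test keeps the
  two computations distinct);
* `evpi_per_person()`:
  $E_\theta[\max_t NB_t(\theta)] - \max_t E_\theta[NB_t(\theta)]$;
* `population_evpi()`: the per-person EVPI times the discounted
  incident population, $\sum_{k=1}^{H} I\,(1+r)^{-(k-1)}$ with the
  default $H = 12$ years, $I = 9{,}000$ patients/year, $r = 0.035$
  (effective multiplier $\approx 10.0017 \times 9{,}000$). Whether the
  first year should also be discounted is not stated in the source
  material; undiscounted-first-year is the default and
  `discount_first_year = TRUE` the alternative (about a 3.4% change).

## The synthetic-data module and the packaged fixture

`simulate_study_set()` draws true study effects from the between-study
bivariate normal and observed effects from the within-study model, with
uniform SEs on a configurable range (the literature gives no
SE-generating mechanism; uniform keeps the simulation transparent) and
arbitrary missingness patterns, returning the generating truth as an
attribute. Defaults describe a small prostate-cancer evidence base:
$\eta_{OS} = \log 0.90$, $\eta_{PFS} = \log 0.64$ (the case study's
pooled magnitudes), $\tau_{OS} = 0.15$, $\tau_{PFS} = 0.30$,
$\rho_b = 0.8$ (PFS effects more heterogeneous than OS and strongly
correlated with them, as expected for a progression-driven disease),
$\rho_w = 0.4$, SEs in $[0.10, 0.22]$ (the magnitude of trials with
100–1,000 patients). `simulate_ipd()` draws Weibull survival times with
exact proportional hazards for the comparator ($S(t)^{HR}$, matching how
hazard ratios act in the Markov engine) and administrative right
censoring.

`hta_fixture()` ships the case-study stand-in. The published articles
print pooled results but not the study-level inputs, so the packaged
study table is synthetic — constructed once so that inverse-variance
pooling of the three mitoxantrone-versus-corticosteroid trials
reproduces the printed pooled hazard ratios (OS 0.903, 0.751–1.084; PFS
0.641, 0.532–0.772) with weights proportional to printed trial sizes,
with the docetaxel trial's OS row at the printed 0.76 (0.620–0.936) and
its PFS blank. Its PFS heterogeneity is moderate (between-study SD
about 0.13); the printed random-effects intervals are wider than this
fixture reproduces. Utilities, the 0.005 other-cause transition,
discounting and EVPI settings are the published values; Weibull
parameters are anchored to the published medians (18 months OS, 6
months PFS on the baseline arm) and the cost blocks are round numbers
of HTA-report magnitude — every approximate field is marked in the YAML
file itself, and file names carry the `_synthetic` suffix.

**What passing tests show — and what they do not.** The generator
produces exactly normal random effects, exactly proportional hazards,
and missingness imposed by design. Calibration results (the 95%
predictive interval for a blanked outcome covering the truth 90–98% of
the time across replicates) therefore validate the *implementation*
under the model's own assumptions. They do not validate the normality
assumption against real trials, where non-linear OS–PFS relationships
can cause overshrinkage; Daniels–Hughes-type models or t-distributed
random effects are the standard alternatives and are out of scope here.
Fixture-based results reproduce the magnitudes of the published
cost-effectiveness tables, not their exact values, because the true
study-level inputs and HTA cost schedules are not public.

## Numerical choices and problem sizes

* $1.959964$ (not 1.96) as the normal 97.5% quantile, keeping
  HR/CI round-trips tight to 6 significant figures.
* A $10^{-10}$ floor on the conditional precision terms in the BRMA
  keeps JAGS stable when $\tau \to 0$ or $|\rho_b| \to 1$; it is orders
  of magnitude below any posterior scale of interest.
* JAGS chains are seeded per chain from the user seed
  (Mersenne–Twister); identical seeds give bit-identical results, a
  tested invariant of the whole pipeline.
* The test suite uses deliberately scaled problem sizes chosen to make
  Monte Carlo error negligible relative to each assertion's tolerance:
  e.g. 100 replicates for the calibration and heterogeneity-recovery
  checks, 20-study synthetic sets, 100,000-person microsimulation, and
  short (3,000–30,000 iteration) chains where sampler precision is not
  what is being tested.
* `run_full_analysis()` joins BRMA prediction draws and pairwise MA
  draws by draw index; the stages are separate MCMC runs, so the join
  treats them as independent posteriors. The original joint
  implementation sampled everything in one model; the factorized
  pipeline makes each stage testable and exposes draws at every
  interface.

## Known limitations

* The within-study correlations are weakly identified; fixing them from
  external knowledge changes the predicted interval and should be
  explored per application.
* No Daniels–Hughes surrogate model, no t-distributed random effects,
  no more-than-two-outcome synthesis, no EVPPI, no tunnel states or
  treatment discontinuation in the Markov models.
* The 2-state and 3-state models share cost inputs; real HTA models
  often differentiate them further.

## A worked run

```{r}
library(metacea)

cfg <- analysis_config(
  mcmc = mcmc_control(30000, 15000, n_chains = 2, seed = 1),
  psa_draws = 2000
)
bundle <- run_full_analysis(config = cfg)

bundle$hr_table                        # pooled, predicted and NMA HRs
bundle$cea$three_state$incremental     # ICER of D+P vs M+P
plot_ceac(bundle$cea$three_state$ceac) # acceptability curves
write_results_tables(bundle, "results")
```
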