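#' Contrast-based network meta-analysis of log hazard ratios
#'
#' Fits a Bayesian normal model to study-level contrasts (log hazard ratio
#' of `comp` versus `ref` per study) with basic parameters relative to a
#' declared baseline treatment, combining direct and indirect evidence
#' through common comparators. The fixed variant assumes no between-study
#' heterogeneity; the random variant adds a common heterogeneity SD with a
#' half-normal prior. Studies not reporting the chosen outcome are dropped
#' unless a predicted estimate has been substituted (see
#' [augment_with_predictions()]).
#'
#' @param studies A [study_table()].
#' @param outcome `"os"` or `"pfs"`.
#' @param variant `"fixed"` or `"random"`.
#' @param baseline Baseline treatment code; defaults to the most frequent
#'   reference code in the network.
#' @param mcmc An [mcmc_control()].
#' @param prior_mean_var Variance of the normal priors on basic parameters.
#' @param prior_tau_var Variance of the half-normal heterogeneity prior
#'   (random variant).
#' @return An object of class `nma_fit` with `draws` (basic parameters
#'   `d[treatment]`), `contrasts` (summaries of every pairwise contrast on
#'   log and HR scale), `diagnostics`, `treatments`, `baseline`, `variant`.
#' @examples
#' \donttest{
#' fx <- hta_fixture()
#' fit <- fit_nma(fx$studies, "os", "fixed",
#'                mcmc = mcmc_control(4000, 1000, 2, seed = 1))
#' fit$contrasts
#' }
#' @export
fit_nma <- function(studies, outcome = c("os", "pfs"),
                    variant = c("fixed", "random"), baseline = NULL,
                    mcmc = mcmc_control(), prior_mean_var = 1e3,
                    prior_tau_var = 1e3) {
  outcome <- match.arg(outcome)
  variant <- match.arg(variant)
  studies <- validate_study_table(studies)
  ycol <- paste0("loghr_", outcome)
  scol <- paste0("se_", outcome)
  dat <- studies[!is.na(studies[[ycol]]), ]
  if (!nrow(dat)) abort(paste0("No studies report ", toupper(outcome), "."))

  trts <- sort(unique(c(dat$ref, dat$comp)))
  if (is.null(baseline)) {
    baseline <- names(sort(table(dat$ref), decreasing = TRUE))[1]
  }
  if (!baseline %in% trts) {
    abort(paste0("Baseline '", baseline, "' is not in the network."))
  }
  trts <- c(baseline, setdiff(trts, baseline))
  check_connected(dat$ref, dat$comp, trts)

  model <- paste0("
  model {
    for (i in 1:Ns) {",
    if (variant == "fixed") "
      y[i] ~ dnorm(d[t[i]] - d[b[i]], 1 / (se[i] * se[i]))" else "
      y[i] ~ dnorm(delta[i], 1 / (se[i] * se[i]))
      delta[i] ~ dnorm(d[t[i]] - d[b[i]], prec_het)", "
    }
    d[1] <- 0
    for (k in 2:K) { d[k] ~ dnorm(0, prior_prec) }",
    if (variant == "random") "
    tau ~ dnorm(0, prior_prec_tau) T(0,)
    prec_het <- 1 / (tau * tau + 1.0E-10)" else "", "
  }")
  data <- list(
    Ns = nrow(dat), K = length(trts),
    y = dat[[ycol]], se = dat[[scol]],
    b = match(dat$ref, trts), t = match(dat$comp, trts),
    prior_prec = 1 / prior_mean_var
  )
  if (variant == "random") data$prior_prec_tau <- 1 / prior_tau_var
  res <- run_jags(
    model, data, params = c("d", if (variant == "random") "tau"),
    mcmc = mcmc,
    inits = function(k) {
      out <- list(d = c(NA, rep(0, length(trts) - 1)))
      if (variant == "random") out$tau <- 0.1
      out
    }
  )

  d_draws <- as.matrix(res$draws[, sprintf("d[%d]", seq_along(trts))])
  colnames(d_draws) <- trts
  pairs <- expand.grid(ref = trts, comp = trts,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$comp, ]
  contrasts <- purrr::pmap(pairs, function(ref, comp) {
    v <- d_draws[, comp] - d_draws[, ref]
    tibble(
      comp = comp, ref = ref, mean = mean(v), sd = sd(v),
      median = median(v),
      q2.5 = unname(quantile(v, 0.025)), q97.5 = unname(quantile(v, 0.975))
    )
  }) |> purrr::list_rbind() |> add_hr_scale()

  converged <- check_convergence(res$diagnostics,
                                 paste0(variant, "-effect NMA"))
  structure(
    list(draws = res$draws, d_draws = d_draws, contrasts = contrasts,
         diagnostics = res$diagnostics, treatments = trts,
         baseline = baseline, variant = variant, outcome = outcome,
         data = dat, converged = converged),
    class = "nma_fit"
  )
}

# Connectivity check by breadth-first search over the contrast graph.
check_connected <- function(ref, comp, trts) {
  adj <- lapply(setNames(trts, trts), function(x) character())
  for (i in seq_along(ref)) {
    adj[[ref[i]]] <- union(adj[[ref[i]]], comp[i])
    adj[[comp[i]]] <- union(adj[[comp[i]]], ref[i])
  }
  seen <- trts[1]
  frontier <- trts[1]
  while (length(frontier)) {
    nxt <- setdiff(unique(unlist(adj[frontier])), seen)
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  if (length(setdiff(trts, seen))) {
    abort(paste0(
      "Network is disconnected: {", paste(seen, collapse = ", "),
      "} is not linked to {", paste(setdiff(trts, seen), collapse = ", "),
      "}."))
  }
  invisible(TRUE)
}

#' Per-draw posterior contrast of two treatments from an NMA fit
#'
#' @param fit An `nma_fit`.
#' @param comp,ref Treatment codes; returns draws of `d[comp] - d[ref]` on
#'   the log HR scale.
#' @return Numeric vector of posterior draws.
#' @export
contrast_draws <- function(fit, comp, ref) {
  stopifnot(inherits(fit, "nma_fit"))
  if (!all(c(comp, ref) %in% fit$treatments)) {
    abort("Both treatments must be in the network.")
  }
  fit$d_draws[, comp] - fit$d_draws[, ref]
}

#' Substitute predicted estimates for missing outcomes
#'
#' Replaces `NA` outcome entries of a study table with the posterior median
#' of the corresponding predicted observed effects from a [fit_brma()] fit,
#' so the study can enter a network meta-analysis. The substituted standard
#' error is the central 95% interval width divided by `2 * 1.959964` rather
#' than the posterior SD: the NMA likelihood treats the estimate as normal,
#' and the interval-based scale is robust to the heavy tails the
#' between-study SD posterior can have when few studies report the
#' outcome. Substituted rows are flagged in a `predicted_<outcome>` column.
#'
#' @param studies A [study_table()].
#' @param brma A `brma_fit` whose `predictions` cover the missing entries.
#' @return The augmented study table with logical columns `predicted_os`,
#'   `predicted_pfs`.
#' @export
augment_with_predictions <- function(studies, brma) {
  studies <- validate_study_table(studies)
  stopifnot(inherits(brma, "brma_fit"))
  studies$predicted_os <- FALSE
  studies$predicted_pfs <- FALSE
  if (!nrow(brma$predictions)) return(studies)
  for (i in seq_len(nrow(brma$predictions))) {
    p <- brma$predictions[i, ]
    j <- which(studies$study_id == p$study_id)
    if (!length(j)) next
    ycol <- paste0("loghr_", p$outcome)
    if (is.na(studies[[ycol]][j])) {
      studies[[ycol]][j] <- p$median
      studies[[paste0("se_", p$outcome)]][j] <- (p$q97.5 - p$q2.5) /
        (2 * .z975)
      studies[[paste0("predicted_", p$outcome)]][j] <- TRUE
    }
  }
  studies
}

#' @export
print.nma_fit <- function(x, ...) {
  cat(sprintf("%s-effect network meta-analysis (%s, %d studies, %d treatments; baseline %s)\n",
              paste0(toupper(substring(x$variant, 1, 1)),
                     substring(x$variant, 2)), toupper(x$outcome),
              nrow(x$data), length(x$treatments), x$baseline))
  vs_base <- x$contrasts[x$contrasts$ref == x$baseline, ]
  for (i in seq_len(nrow(vs_base))) {
    r <- vs_base[i, ]
    cat(sprintf("  %s vs %s: HR %.3f (95%% CrI %.3f-%.3f)\n",
                r$comp, r$ref, r$hr, r$hr_q2.5, r$hr_q97.5))
  }
  invisible(x)
}

#' @export
tidy.nma_fit <- function(x, ...) x$contrasts

#' @export
glance.nma_fit <- function(x, ...) {
  tibble(
    outcome = x$outcome, variant = x$variant,
    n_studies = nrow(x$data), n_treatments = length(x$treatments),
    n_draws = nrow(x$draws),
    min_ess = min(x$diagnostics$ess),
    max_rhat = suppressWarnings(max(x$diagnostics$rhat, na.rm = TRUE)),
    converged = x$converged
  )
}
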