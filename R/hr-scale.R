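#' Convert hazard ratios with confidence limits to the log scale
#'
#' Treatment effects on survival outcomes are synthesised on the log hazard
#' ratio scale, where estimates are approximately normal. `hr_ci_to_log()`
#' maps a hazard ratio and its 95% confidence (or credible) interval to a
#' point estimate and standard error on that scale; `loghr_to_hr_ci()` is the
#' inverse. The interval is assumed symmetric on the log scale, so
#' `se = (log(upper) - log(lower)) / (2 * 1.959964)`.
#'
#' @param hr,lower,upper Positive hazard ratio and 95% interval limits.
#'   Vectorised; `lower <= hr <= upper` elementwise.
#' @return A tibble with columns `loghr` and `se`.
#' @examples
#' hr_ci_to_log(0.76, 0.620, 0.936)
#' @export
hr_ci_to_log <- function(hr, lower, upper) {
  if (any(!is.finite(hr) | !is.finite(lower) | !is.finite(upper)) ||
      any(hr <= 0 | lower <= 0 | upper <= 0)) {
    abort("`hr`, `lower` and `upper` must all be positive and finite.")
  }
  if (any(lower > hr | hr > upper)) {
    abort("Interval limits must satisfy `lower <= hr <= upper`.")
  }
  tibble(loghr = log(hr), se = (log(upper) - log(lower)) / (2 * .z975))
}

#' @rdname hr_ci_to_log
#' @param loghr,se Log hazard ratio and its standard error (`se > 0`).
#' @return For `loghr_to_hr_ci()`, a tibble with columns `hr`, `lower`,
#'   `upper`.
#' @export
loghr_to_hr_ci <- function(loghr, se) {
  if (any(!is.finite(loghr)) || any(!is.finite(se) | se <= 0)) {
    abort("`loghr` must be finite and `se` positive.")
  }
  tibble(
    hr = exp(loghr),
    lower = exp(loghr - .z975 * se),
    upper = exp(loghr + .z975 * se)
  )
}
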