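#' Plot cost-effectiveness acceptability curves
#'
#' One curve per treatment: probability of attaining the greatest net
#' benefit against the willingness-to-pay threshold.
#'
#' @param x A `ceac` tibble from [ceac()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_ceac <- function(x, ...) {
  stopifnot(inherits(x, "ceac") || all(c("wtp", "treatment",
                                         "probability") %in% names(x)))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$wtp, y = .data$probability,
                                  colour = .data$treatment)) +
    ggplot2::geom_line(linewidth = 0.7) +
    ggplot2::scale_y_continuous(limits = c(0, 1)) +
    ggplot2::labs(
      x = "Willingness to pay (GBP per QALY)",
      y = "Probability cost-effective",
      colour = "Treatment"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.ceac <- function(object, ...) plot_ceac(object, ...)

#' Plot the cost-effectiveness plane
#'
#' Scatter of per-draw incremental cost against incremental QALY for
#' `comp` versus `ref`, with the origin marked.
#'
#' @param psa A `psa_result`.
#' @param ref,comp Treatment codes.
#' @param wtp Optional threshold; if given, a line of slope `wtp` through
#'   the origin is added.
#' @return A ggplot object.
#' @export
plot_ce_plane <- function(psa, ref, comp, wtp = NULL) {
  wide <- psa_wide(psa, c(ref, comp))
  dat <- tibble(
    delta_cost = wide$cost[, comp] - wide$cost[, ref],
    delta_qaly = wide$qaly[, comp] - wide$qaly[, ref]
  )
  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$delta_qaly,
                                         y = .data$delta_cost)) +
    ggplot2::geom_point(alpha = 0.25, size = 0.7) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::labs(
      x = sprintf("Incremental QALYs (%s vs %s)", comp, ref),
      y = "Incremental cost (GBP)"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(wtp)) {
    p <- p + ggplot2::geom_abline(slope = wtp, intercept = 0,
                                  linetype = 3)
  }
  p
}

#' @export
autoplot.psa_result <- function(object, ref = NULL, comp = NULL, ...) {
  trts <- unique(as_tibble(object)$treatment)
  if (is.null(ref)) ref <- trts[1]
  if (is.null(comp)) comp <- trts[2]
  plot_ce_plane(object, ref, comp, ...)
}
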