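# ggplot2 methods for result objects.

#' Plot an accumulation curve
#'
#' Mean statistic against sample size with the 2.5-97.5 percentile envelope
#' of the subsample replicates.
#'
#' @param object An `accum_curve` tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.accum_curve <- function(object, ...) {
  lab <- switch(attr(object, "statistic") %||% "alleles",
                alleles = "Unique alleles",
                shannon = "Shannon-Weaver H'")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$n, y = .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$q2.5, ymax = .data$q97.5),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "Sample size (individuals)", y = lab) +
    ggplot2::theme_minimal()
}

#' Plot a Michaelis-Menten accumulation fit
#'
#' Observed points, the fitted saturation curve, and the `Dmax` asymptote.
#'
#' @param object An `mm_fit` object.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.mm_fit <- function(object, ...) {
  grid <- tibble::tibble(n = seq(0, max(object$data$n) * 1.5, length.out = 200))
  grid$D <- object$dmax * grid$n / (object$k_half + grid$n)
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$n, y = .data$D)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::geom_hline(yintercept = object$dmax, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::labs(x = "Sample size (individuals)", y = "Diversity",
                  subtitle = sprintf("Dmax = %.2f, K1/2 = %.2f",
                                     object$dmax, object$k_half)) +
    ggplot2::theme_minimal()
}

#' Plot per-population diversity summaries
#'
#' @param summary Output of [diversity_summary()].
#' @param metric Column to plot (`"ar"`, `"ho"`, `"he"`, `"n_alleles"`).
#' @return A ggplot.
#' @export
plot_diversity <- function(summary, metric = "ar") {
  ggplot2::ggplot(summary,
                  ggplot2::aes(x = .data$population, y = .data[[metric]],
                               fill = .data$locus)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = toupper(metric)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
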