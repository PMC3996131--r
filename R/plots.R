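# ggplot2 displays for screen and sweep results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot the radius sweep
#'
#' Bivariate correlation of the swept metric with the outcome against network
#' radius, with the peak radius marked.
#' @param object a `severance_sweep`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.severance_sweep <- function(object, ...) {
  curve <- object$curve
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$radius_m, y = .data$r)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 3, colour = "grey50") +
    ggplot2::geom_line(colour = "steelblue4") +
    ggplot2::geom_point(size = 1.6, colour = "steelblue4") +
    ggplot2::geom_vline(xintercept = object$peak_radius_m,
                        linetype = 2, colour = "firebrick") +
    ggplot2::labs(
      x = "Network radius (m)",
      y = sprintf("Pearson r (%s vs %s)", object$metric, object$outcome),
      title = sprintf("Scale dependence of the %s association", object$metric),
      subtitle = sprintf("peak |r| at %d m", as.integer(object$peak_radius_m))
    ) +
    ggplot2::theme_minimal()
}

#' Plot the correlation screen grid
#'
#' Heatmap of Pearson r over the metric-by-radius grid; cells significant
#' after Bonferroni correction (adjusted p < 0.05) are outlined.
#' @param object a `severance_screen`
#' @param ... unused
#' @return a ggplot
#' @export
autoplot.severance_screen <- function(object, ...) {
  g <- object$grid
  g$metric <- factor(g$metric, levels = rev(unique(g$metric)))
  g$sig <- !is.na(g$p_bonferroni) & g$p_bonferroni < 0.05
  ggplot2::ggplot(g, ggplot2::aes(x = factor(.data$radius_m), y = .data$metric,
                                  fill = .data$r)) +
    ggplot2::geom_tile(colour = "white") +
    ggplot2::geom_tile(data = g[g$sig, , drop = FALSE], fill = NA,
                       colour = "black", linewidth = 0.7) +
    ggplot2::scale_fill_gradient2(low = "darkorange3", mid = "white",
                                  high = "steelblue4", na.value = "grey85") +
    ggplot2::labs(x = "Network radius (m)", y = NULL, fill = "r",
                  title = sprintf("Correlation screen vs %s", object$outcome)) +
    ggplot2::theme_minimal()
}
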