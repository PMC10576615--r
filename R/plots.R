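#' Plot the effect-size-ratio frequency distribution
#'
#' Bar histogram of apoB : TRL/remnant-C effect-size ratios with the two
#' cluster intervals shaded, mirroring the inspection plot that motivates
#' the two-cluster rule.
#'
#' @param object A [ratio_histogram()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot ratio_histogram
#' @export
autoplot.ratio_histogram <- function(object, ...) {
  bins <- object$bins
  shade <- tibble::tibble(
    xmin = c(0.9, -0.75), xmax = c(3.0, 0.75),
    cluster = c("cluster 1", "cluster 2"))
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$mid, y = .data$count)) +
    ggplot2::geom_rect(
      data = shade, inherit.aes = FALSE, alpha = 0.15,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = 0, ymax = Inf, fill = .data$cluster)) +
    ggplot2::geom_col(width = diff(bins$mid[1:2]) * 0.95) +
    ggplot2::labs(x = "apoB : TRL/remnant-C effect-size ratio",
                  y = "variants", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-decile hazard ratios
#'
#' Decile hazard ratios (95% CI) against the decile mean apoB, the standard
#' presentation for a polygenic-score gradient.
#'
#' @param object A [decile_hazards()] result.
#' @param decile_means Optional [decile_summary()] table; when supplied the
#'   x axis is the decile mean apoB (g/L), otherwise the decile index.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot decile_hazards
#' @export
autoplot.decile_hazards <- function(object, decile_means = NULL, ...) {
  tab <- object$table
  if (!is.null(decile_means)) {
    tab <- dplyr::inner_join(tab, decile_means[, c("decile", "mean_apob")],
                             by = "decile")
    tab$x <- tab$mean_apob
    xlab <- "decile mean apoB (g/L)"
  } else {
    tab$x <- tab$decile
    xlab <- "score decile"
  }
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$x, y = .data$hr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$ci_low,
                                          ymax = .data$ci_high)) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = xlab, y = "hazard ratio (ref: decile 1)") +
    ggplot2::theme_minimal()
}

#' Plot a fitted ratio-spline hazard curve
#'
#' @param object A [ratio_spline()] fit.
#' @param ... Unused.
#' @return A ggplot of the hazard ratio along the exposure-ratio grid,
#'   normalised to 1 at the reference ratio.
#' @method autoplot ratio_spline
#' @export
autoplot.ratio_spline <- function(object, ...) {
  ggplot2::ggplot(object$curve, ggplot2::aes(x = .data$ratio, y = .data$hr)) +
    ggplot2::geom_hline(yintercept = 1, linetype = 2, colour = "grey50") +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$reference_ratio,
                        linetype = 3, colour = "grey50") +
    ggplot2::labs(
      x = object$exposure,
      y = "hazard ratio",
      subtitle = sprintf("%s adjustment, spline p = %.2g",
                         if (object$include_hdl) "with HDL-C" else
                           "without HDL-C",
                         object$p_spline)) +
    ggplot2::theme_minimal()
}

#' Scatter plot of per-variant apoB vs TRL/remnant-C effects by cluster
#'
#' @param oriented Output of [orient_effects()] (minor-vs-major mode) with
#'   `beta_trl_remnant_c` and `beta_apob` columns.
#' @param clusters A [cluster_assignments()] tibble.
#' @return A ggplot.
#' @export
plot_effect_clusters <- function(oriented, clusters) {
  d <- dplyr::inner_join(oriented, clusters, by = "variant_id")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$beta_trl_remnant_c,
                                  y = .data$beta_apob,
                                  colour = .data$cluster)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey80") +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "TRL/remnant-C effect (mmol/L per minor allele)",
                  y = "apoB effect (g/L per minor allele)",
                  colour = "cluster") +
    ggplot2::theme_minimal()
}
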