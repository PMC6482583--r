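# ggplot2 views of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a threshold fit
#'
#' For the (G,F)-classifier, a heatmap of relative mutual information over
#' the (glucose, formate) threshold grid with the optimum marked; for the
#' F-classifier, the rmi profile along the formate-threshold axis.
#'
#' @param object A `threshold_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot threshold_fit
#' @export
autoplot.threshold_fit <- function(object, ...) {
  if (object$classifier == "GF") {
    ggplot2::ggplot(object$grid,
                    ggplot2::aes(x = .data$f_t, y = .data$g_t,
                                 fill = .data$rmi)) +
      ggplot2::geom_tile() +
      ggplot2::geom_point(data = glance(object),
                          ggplot2::aes(x = .data$f_t, y = .data$g_t),
                          inherit.aes = FALSE, colour = "white", shape = 4,
                          size = 3) +
      ggplot2::scale_fill_viridis_c(name = "rmi") +
      ggplot2::labs(x = "formate threshold (mM)",
                    y = "glucose threshold (peak area)",
                    title = "Relative mutual information over the threshold grid")
  } else {
    ggplot2::ggplot(object$grid, ggplot2::aes(x = .data$f_t, y = .data$rmi)) +
      ggplot2::geom_step() +
      ggplot2::geom_vline(xintercept = object$f_t, linetype = "dashed") +
      ggplot2::labs(x = "formate threshold (mM)",
                    y = "relative mutual information",
                    title = "F-classifier threshold profile")
  }
}

#' Plot ROC points
#'
#' Draws an ROC curve (F-classifier sweep) or the attainable ROC region
#' ((G,F)-classifier grid) in the (FPR, TPR) plane, with the chance diagonal.
#'
#' @param points A tibble from [roc_curve_f()] or [roc_region_gf()].
#' @return A ggplot object.
#' @export
plot_roc <- function(points) {
  p <- ggplot2::ggplot(points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey50")
  p <- if ("g_t" %in% names(points)) {
    p + ggplot2::geom_point(alpha = 0.25, size = 0.8, colour = "#8c510a")
  } else {
    p + ggplot2::geom_step(colour = "#8c510a") +
      ggplot2::geom_point(size = 0.8, colour = "#8c510a")
  }
  p + ggplot2::coord_equal(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "false positive rate", y = "true positive rate")
}

#' Plot cross-validation performance estimates
#'
#' Medians with 5-95% ranges per metric.
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot cv_result
#' @export
autoplot.cv_result <- function(object, ...) {
  ggplot2::ggplot(object$estimates,
                  ggplot2::aes(x = .data$metric, y = .data$median)) +
    ggplot2::geom_pointrange(ggplot2::aes(ymin = .data$lo, ymax = .data$hi)) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "rate (median, 5-95%)",
                  title = sprintf("%s-classifier, p_o = %g",
                                  object$config$classifier,
                                  object$config$p_o))
}

#' Volcano plot of differential statistics
#'
#' Fold change (log2 axis) versus -log10 p-value, coloured by significance
#' tier.
#'
#' @param volcano A tibble from [welch_volcano()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(volcano) {
  dat <- dplyr::filter(volcano, !is.na(.data$p_value),
                       !is.na(.data$fold_change))
  ggplot2::ggplot(dat, ggplot2::aes(x = log2(.data$fold_change),
                                    y = -log10(.data$p_value),
                                    colour = .data$tier)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = c(3, 6), linetype = "dashed",
                        colour = "grey60") +
    ggplot2::labs(x = "log2 fold change (case / control)",
                  y = "-log10 p (Welch)", colour = "tier")
}
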