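# ggplot2 visualisations of the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @method autoplot pcm_roc
#' @export
autoplot.pcm_roc <- function(object, ...) {
  pts <- object$points
  ggplot2::ggplot(pts, ggplot2::aes(x = 1 - .data$specificity,
                                    y = .data$sensitivity)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_step(linewidth = 0.7) +
    ggplot2::annotate("text", x = 0.75, y = 0.1,
                      label = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = "Interacting vs non-interacting classification") +
    ggplot2::theme_minimal()
}

#' @method autoplot pcm_cv
#' @export
autoplot.pcm_cv <- function(object, ...) {
  ggplot2::ggplot(object$predictions,
                  ggplot2::aes(x = .data$pkd, y = .data$predicted,
                               colour = .data$inactive)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::labs(
      x = "observed pKd", y = "predicted pKd", colour = "censored",
      title = sprintf("%s (%s): %s = %.3f", object$method, object$mode,
                      object$metric, object$p2)) +
    ggplot2::theme_minimal()
}

#' @method autoplot pcm_error_hist
#' @export
autoplot.pcm_error_hist <- function(object, ...) {
  bins <- object$bins
  bins$label <- sprintf("(%.2g, %.2g]", bins$lower, bins$upper)
  bins$label <- factor(bins$label, levels = bins$label)
  ggplot2::ggplot(bins, ggplot2::aes(x = .data$label, y = .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "|prediction error| (pKd units)", y = "pairs",
                  title = "Distribution of prediction errors") +
    ggplot2::theme_minimal()
}

#' @method autoplot pcm_size_sweep
#' @export
autoplot.pcm_size_sweep <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$fraction, y = .data$mean_p2)) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_p2 - .data$sd_p2,
      ymax = .data$mean_p2 + .data$sd_p2)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "training fraction", y = object$metric,
                  title = "Performance vs dataset size") +
    ggplot2::theme_minimal()
}

#' Score plot of a PCA model
#'
#' @param object A `pcm_pca` model.
#' @param components Two component indices to plot.
#' @param groups Optional grouping vector for colouring (e.g. kinase
#'   groups).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_scores <- function(object, components = c(1, 2), groups = NULL, ...) {
  stopifnot(inherits(object, "pcm_pca"))
  df <- tibble::tibble(
    x = object$scores[, components[1]],
    y = object$scores[, components[2]]
  )
  if (!is.null(groups)) df$group <- groups
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  100 * object$explained_variance[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  100 * object$explained_variance[components[2]])) +
    ggplot2::theme_minimal()
  if (is.null(groups)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
  }
}
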