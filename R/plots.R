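# ggplot2 views of the result objects. Each autoplot returns a plain ggplot
# the caller can restyle.

#' @describeIn confusion_matrix Heatmap of the (optionally row-normalized)
#'   confusion matrix.
#' @param object The object to plot.
#' @method autoplot os_confusion
#' @export
autoplot.os_confusion <- function(object, normalize = TRUE, ...) {
  df <- tidy(object, normalize = normalize)
  lv <- rownames(object)
  df$truth <- factor(df$truth, levels = rev(lv))
  df$predicted <- factor(df$predicted, levels = lv)
  ggplot2::ggplot(df, ggplot2::aes(.data$predicted, .data$truth,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = ifelse(
      .data$value > 0,
      formatC(.data$value, digits = if (normalize) 2 else 0,
              format = if (normalize) "f" else "d"), "")),
      size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7fb8",
                                 limits = c(0, NA)) +
    ggplot2::labs(x = "predicted", y = "truth",
                  fill = if (normalize) "rate" else "count") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @describeIn roc_pr_curves One-vs-rest ROC curves (all labels + micro
#'   average).
#' @param object The object to plot.
#' @param which `"roc"` or `"pr"`.
#' @param ... Unused.
#' @method autoplot os_curves
#' @export
autoplot.os_curves <- function(object, which = c("roc", "pr"), ...) {
  which <- match.arg(which)
  if (which == "roc") {
    ggplot2::ggplot(object$roc, ggplot2::aes(.data$fpr, .data$tpr,
                                             colour = .data$label)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                           colour = "grey60") +
      ggplot2::geom_line() +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "false positive rate", y = "true positive rate") +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(object$pr, ggplot2::aes(.data$recall, .data$precision,
                                            colour = .data$label)) +
      ggplot2::geom_step(direction = "vh") +
      ggplot2::coord_equal() +
      ggplot2::labs(x = "recall", y = "precision") +
      ggplot2::theme_minimal()
  }
}

#' @describeIn threshold_sweep Threshold-vs-accuracy line plot.
#' @param object The object to plot.
#' @method autoplot threshold_sweep
#' @export
autoplot.threshold_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$threshold, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "rejection threshold ε", y = "accuracy") +
    ggplot2::theme_minimal()
}

#' @describeIn tail_diagnostics Per-class empirical vs fitted CDF panels.
#' @param object The object to plot.
#' @method autoplot tail_diagnostics
#' @export
autoplot.tail_diagnostics <- function(object, ...) {
  df <- tidyr::pivot_longer(object, c("empirical_cdf", "fitted_cdf"),
                            names_to = "kind", values_to = "cdf")
  ggplot2::ggplot(df, ggplot2::aes(.data$distance, .data$cdf,
                                   colour = .data$kind)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~label, scales = "free_x") +
    ggplot2::labs(x = "distance to MAV", y = "CDF", colour = NULL) +
    ggplot2::theme_minimal()
}
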