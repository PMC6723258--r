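#' Plot a precision-recall curve
#'
#' @param object a [pr_curve()].
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.pr_curve <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("autoplot requires the ggplot2 package")
  df <- as.data.frame(object)
  df <- df[order(df$recall), ]
  ggplot2::ggplot(df, ggplot2::aes(x = recall, y = precision)) +
    ggplot2::geom_step(direction = "vh") +
    ggplot2::geom_point(size = 1) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      title = sprintf("Precision-recall at IoU threshold %.2f (%s)",
                      attr(object, "t_iou"), attr(object, "mode")),
      x = "Recall", y = "Precision") +
    ggplot2::theme_minimal()
}

#' Plot AP against the IoU threshold grid for each matching mode
#'
#' @param object an [evaluate_suite()] report.
#' @param ... unused.
#' @return a ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.eval_report <- function(object, ...) {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop("autoplot requires the ggplot2 package")
  ggplot2::ggplot(object$ap,
                  ggplot2::aes(x = t_iou, y = ap, colour = mode)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "IoU threshold", y = "Average precision",
                  colour = "Matching") +
    ggplot2::theme_minimal()
}
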