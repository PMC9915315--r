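#' Plot the weight-sweep curve
#'
#' F-measure of the weighted integration as a function of the blending
#' weight `w`, with the pure text-classifier method at `w = 0` and the pure
#' rule method at `w = 1`.
#'
#' @param sweep a [sweep_weight()] table.
#' @return A ggplot object.
#' @export
plot_weight_sweep <- function(sweep) {
  need_ggplot2()
  ggplot2::ggplot(sweep, ggplot2::aes(x = .data$w, y = .data$f_measure)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(sweep, "best_w"),
                        linetype = "dashed") +
    ggplot2::labs(x = "rule weight w", y = "F-measure",
                  title = "Weighted integration performance") +
    ggplot2::theme_minimal()
}

#' Plot grouped F-measures
#'
#' Per-group F-measure curves per method, in the layout used for the
#' word-count, address/contact, and attention analyses.
#'
#' @param report a [grouped_evaluation()] table.
#' @param xlab x-axis label.
#' @return A ggplot object.
#' @export
plot_group_f <- function(report, xlab = "group") {
  need_ggplot2()
  ggplot2::ggplot(report,
                  ggplot2::aes(x = .data$group, y = .data$f_measure,
                               colour = .data$method)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = xlab, y = "F-measure") +
    ggplot2::theme_minimal()
}

need_ggplot2 <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting", call. = FALSE)
  }
}
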