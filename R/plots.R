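#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a DVH curve
#'
#' @param object A `dvh_curve` (from [cumulative_dvh()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dvh_curve
#' @export
autoplot.dvh_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dose / 100, y = .data$volume_pct)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)", title = "Cumulative DVH") +
    ggplot2::theme_minimal()
}

#' Plot the per-case DVH comparison of an evaluation report
#'
#' Clinical (solid) versus predicted (dashed) DVH for every structure.
#'
#' @param object A `dose_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot dose_eval
#' @export
autoplot.dose_eval <- function(object, ...) {
  ggplot2::ggplot(object$dvh,
                  ggplot2::aes(x = .data$dose / 100, y = .data$volume_pct,
                               colour = .data$structure,
                               linetype = .data$source)) +
    ggplot2::geom_step(direction = "hv") +
    ggplot2::scale_linetype_manual(values = c(clinical = "solid",
                                              predicted = "dashed")) +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)",
                  title = "Clinical vs predicted DVH") +
    ggplot2::theme_minimal()
}

#' Plot a dose-difference histogram
#'
#' @param object A `diff_histogram` (from [difference_histogram()]).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot diff_histogram
#' @export
autoplot.diff_histogram <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin_mid, y = .data$count)) +
    ggplot2::geom_col(width = diff(object$bin_mid[1:2])) +
    ggplot2::labs(
      x = "Predicted - clinical dose (cGy)", y = "Voxels",
      title = sprintf("Difference histogram (bias %.1f cGy, sd %.1f cGy)",
                      attr(object, "bias"), attr(object, "sd"))) +
    ggplot2::theme_minimal()
}

#' Plot training loss curves
#'
#' @param object An `fd_fit` (from [train_adversarial()]).
#' @param ... Unused.
#' @return A ggplot of every loss term by epoch.
#' @method autoplot fd_fit
#' @export
autoplot.fd_fit <- function(object, ...) {
  long <- tidy(object)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$term)) +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "Epoch", y = "Loss (log scale)",
                  title = "Adversarial training losses") +
    ggplot2::theme_minimal()
}
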