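#' Plot a trajectory
#'
#' Faceted time courses of the state variables (and total cells), with
#' infusion cycles shaded.
#'
#' @param object A `folfiri_trajectory`.
#' @param vars Variables to show (default: all 17 plus `total_cells`).
#' @param log_y Use a log10 y-axis?
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot folfiri_trajectory
#' @export
autoplot.folfiri_trajectory <- function(object,
                                        vars = c(STATE_NAMES, "total_cells"),
                                        log_y = FALSE, ...) {
  d <- tidy(object) |> dplyr::filter(.data$variable %in% vars)
  reg <- attr(object, "regimen")
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$time_days, y = .data$value)) +
    ggplot2::geom_line(color = "#2c7fb8") +
    ggplot2::facet_wrap(~variable, scales = "free_y") +
    ggplot2::labs(x = "time (days)", y = "dimensionless density") +
    ggplot2::theme_minimal()
  if (!is.null(reg) && reg$n_cycles > 0) {
    p <- p + ggplot2::annotate(
      "rect", xmin = reg$start_day, xmax = treatment_end_day(reg),
      ymin = -Inf, ymax = Inf, alpha = 0.08, fill = "red")
  }
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' Plot a scan result
#'
#' Cancer (and total-cell) summaries against the scan axis, one line per
#' evaluation day.
#'
#' @param object A `folfiri_scan`.
#' @param output `"cancer"` or `"total_cells"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot folfiri_scan
#' @export
autoplot.folfiri_scan <- function(object, output = c("cancer", "total_cells"),
                                  ...) {
  output <- match.arg(output)
  axis <- attr(object, "axis")
  d <- tibble::as_tibble(object)
  if (is.numeric(d[[axis]])) {
    ggplot2::ggplot(d, ggplot2::aes(x = .data[[axis]], y = .data[[output]],
                                    color = factor(.data$eval_day))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(color = "evaluation day", y = output) +
      ggplot2::theme_minimal()
  } else {
    ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$eval_day),
                                    y = .data[[output]],
                                    fill = .data[[axis]])) +
      ggplot2::geom_col(position = "dodge") +
      ggplot2::labs(x = "evaluation day", y = output, fill = axis) +
      ggplot2::theme_minimal()
  }
}

#' Plot a ROC curve
#'
#' @param object A `folfiri_roc`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot folfiri_roc
#' @export
autoplot.folfiri_roc <- function(object, ...) {
  d <- object$sweep[order(object$sweep$fpr, object$sweep$tpr), ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                         color = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "false positive rate", y = "true positive rate",
                  title = sprintf("AUC = %.3f", object$auc)) +
    ggplot2::theme_minimal()
}
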