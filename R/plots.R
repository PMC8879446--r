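#' Plot per-increment accuracy and F1 for a run history
#'
#' @param object An `mdcl_history`.
#' @param ... Unused.
#' @return A ggplot of cumulative-test metrics against the increment axis.
#' @export
autoplot.mdcl_history <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object$increments[, c("increment", "accuracy", "f1")],
    cols = c("accuracy", "f1"), names_to = "metric", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$increment, .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(df$increment)) +
    ggplot2::labs(x = "increment", y = "cumulative-test value",
                  title = "Incremental classification performance") +
    ggplot2::theme_minimal()
}

#' Plot a temperature sweep
#'
#' @param object A [tau_sweep()] result.
#' @param ... Unused.
#' @return A ggplot of mean top-1 test error (with +/- 1 sd ribbon) against
#'   the temperature.
#' @export
autoplot.tau_sweep <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$tau, .data$mean_error)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean_error - .data$sd_error,
                   ymax = .data$mean_error + .data$sd_error),
      alpha = 0.2
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(tau), y = "top-1 test error",
                  title = "Effect of the softening temperature") +
    ggplot2::theme_minimal()
}

#' Plot a forgetting curve
#'
#' @param object A [forgetting_curve()] result.
#' @param ... Unused.
#' @return A ggplot of per-class accuracy drops by increment over the series.
#' @export
autoplot.forgetting_curve <- function(object, ...) {
  ggplot2::ggplot(object$series,
                  ggplot2::aes(.data$increment, .data$accuracy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = unique(object$series$increment)) +
    ggplot2::labs(x = "increment", y = "cumulative top-1 accuracy",
                  title = "Forgetting curve") +
    ggplot2::theme_minimal()
}

#' Plot step-level loss components from a training log
#'
#' @param log The `log` tibble of an `mdcl_history` (or [train_increment()]).
#' @return A ggplot of each loss component over optimisation steps.
#' @export
plot_loss_log <- function(log) {
  df <- dplyr::mutate(log, global_step = dplyr::row_number())
  df <- tidyr::pivot_longer(df, cols = c("l_md", "l_o", "l_n", "l_cl"),
                            names_to = "component", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(.data$global_step, .data$value,
                                   colour = .data$component)) +
    ggplot2::geom_line(alpha = 0.8) +
    ggplot2::labs(x = "step", y = "loss", title = "Continual loss components") +
    ggplot2::theme_minimal()
}
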