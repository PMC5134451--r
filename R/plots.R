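# ggplot2 presentation methods

#' Plot the foot-to-foot distance signal with detected cycle boundaries
#'
#' @param skeleton A skeleton tibble (or [simulate_gait()] object).
#' @param alpha,window,min_cycle_frames Segmentation settings, as in
#'   [extract_cycles()].
#' @return A ggplot object: raw and smoothed distance with boundary frames.
#' @export
plot_foot_distance <- function(skeleton, alpha = 0.2, window = 5,
                               min_cycle_frames = 10) {
  if (inherits(skeleton, "gait_simulation")) skeleton <- skeleton$skeleton
  cycles <- extract_cycles(skeleton, alpha, window, min_cycle_frames)
  sig <- attr(cycles, "signal")
  long <- tidyr::pivot_longer(sig, c("raw", "smoothed"),
                              names_to = "signal", values_to = "distance")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$frame, y = .data$distance,
                                     colour = .data$signal)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = attr(cycles, "boundary_frames"),
                        linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "frame", y = "foot-to-foot distance (m)",
                  title = "Gait cycle segmentation") +
    ggplot2::theme_minimal()
}

#' @describeIn roc_auc_eer ROC curve with the chance diagonal and EER point.
#' @param object A `gait_roc`.
#' @param ... Unused.
#' @export
autoplot.gait_roc <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted") +
    ggplot2::geom_step() +
    ggplot2::annotate("point", x = object$eer, y = 1 - object$eer,
                      colour = "red") +
    ggplot2::labs(
      x = "false positive rate (1 - specificity)",
      y = "true positive rate (sensitivity)",
      title = sprintf("ROC: AUC = %.3f, EER = %.3f", object$auc, object$eer)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn grid_search Accuracy heatmap over the (states, codewords) grid.
#' @param object A `gait_grid`.
#' @export
autoplot.gait_grid <- function(object, ...) {
  ggplot2::ggplot(object$grid,
                  ggplot2::aes(x = .data$k, y = .data$n_states,
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(data = tibble::as_tibble(object$best), size = 2) +
    ggplot2::labs(x = "observations (codewords)", y = "states",
                  fill = "accuracy",
                  title = "Model selection grid") +
    ggplot2::theme_minimal()
}

#' @describeIn fit_normality_model Histogram of training log-likelihoods
#'   with the learned threshold.
#' @param object A `normality_model`.
#' @export
autoplot.normality_model <- function(object, ...) {
  df <- tibble::tibble(zeta = object$train_loglik)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zeta)) +
    ggplot2::geom_histogram(bins = 30, fill = "grey70", colour = "grey30") +
    ggplot2::geom_vline(xintercept = object$threshold, colour = "red") +
    ggplot2::geom_vline(xintercept = object$mu, linetype = "dashed") +
    ggplot2::labs(x = "training log-likelihood",
                  title = sprintf("Normality threshold %.2f = mu %.2f + (%.2f) x sigma %.2f",
                                  object$threshold, object$mu, object$lambda,
                                  object$sigma)) +
    ggplot2::theme_minimal()
}

#' @describeIn run_end_to_end Log-likelihood distributions of evaluated
#'   cycles by true class, with the decision threshold.
#' @param object A `gait_screen`.
#' @export
autoplot.gait_screen <- function(object, ...) {
  ggplot2::ggplot(object$cycles,
                  ggplot2::aes(x = .data$zeta, fill = .data$truth)) +
    ggplot2::geom_histogram(bins = 40, alpha = 0.6, position = "identity") +
    ggplot2::geom_vline(xintercept = object$model$threshold, colour = "red") +
    ggplot2::labs(x = "cycle log-likelihood",
                  title = "Normal vs abnormal cycle scores") +
    ggplot2::theme_minimal()
}
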