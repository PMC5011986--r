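#' Plot a fitted reference model
#'
#' Per-frame mean of each shape feature with a ±1 SD ribbon, showing the
#' drift toward mitotic rounding (`lambda1_norm`, `lambda2_norm` toward
#' 1/3, `skewness` toward 0 as `tau` approaches -1).
#'
#' @param object a `reference_model`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot reference_model
#' @export
autoplot.reference_model <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$mean)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      alpha = 0.25
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "frames before division (tau)",
                  y = "feature value (mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Plot LOOCV predictions against truth
#'
#' Per-`tau` mean ± SD of the posterior-mean estimate (Bayes) and the MLE
#' against the identity line.
#'
#' @param object a `loocv_report`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot loocv_report
#' @export
autoplot.loocv_report <- function(object, ...) {
  df <- object$per_tau |>
    tidyr::pivot_longer(
      cols = c("mean_bayes", "sd_bayes", "mean_mle", "sd_mle"),
      names_to = c(".value", "method"), names_pattern = "(mean|sd)_(.*)"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$mean,
                                   colour = .data$method)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(width = 0.4), fatten = 1.5
    ) +
    ggplot2::labs(x = "true frames before division (tau)",
                  y = "predicted tau (mean ± SD)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Histogram of prediction errors by method
#'
#' Counts of integer-rounded frame deviations (`tau_hat - tau`) for the
#' sequential Bayes and MLE estimators, side by side.
#'
#' @param report a `loocv_report`.
#' @return A ggplot object.
#' @export
plot_error_histogram <- function(report) {
  stopifnot(inherits(report, "loocv_report"))
  ggplot2::ggplot(report$histogram,
                  ggplot2::aes(x = .data$deviation, y = .data$count,
                               fill = .data$method)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "deviation (frames)", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a posterior over remaining frames
#'
#' @param object a `posterior_state`.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot posterior_state
#' @export
autoplot.posterior_state <- function(object, ...) {
  df <- tibble::tibble(tau = object$taus, prob = object$probs)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$prob)) +
    ggplot2::geom_col() +
    ggplot2::geom_vline(xintercept = sum(object$taus * object$probs),
                        linetype = "dashed") +
    ggplot2::labs(
      x = "frames before division (tau)", y = "posterior probability",
      title = sprintf("observation step %d", object$step)
    ) +
    ggplot2::theme_minimal()
}

#' Plot cohort trajectories in feature space
#'
#' One line per cell per feature against `tau`, with the cohort mean
#' overlaid — the raw material the reference model is fitted from.
#'
#' @param features cohort feature table.
#' @return A ggplot object.
#' @export
plot_trajectory_features <- function(features) {
  check_feature_frame(features)
  df <- features |>
    tidyr::pivot_longer(dplyr::all_of(feature_cols),
                        names_to = "feature", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$tau, y = .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$cell_id),
                       alpha = 0.25, linewidth = 0.3) +
    ggplot2::stat_summary(fun = mean, geom = "line",
                          colour = "red", linewidth = 0.8) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "frames before division (tau)", y = "feature value") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
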