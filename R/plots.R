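#' Plot a rejection curve
#'
#' Accuracy as a function of the fraction of most-uncertain epochs removed.
#'
#' @param object A `rejection_curve`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.rejection_curve <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            dplyr::all_of(c("per_subject_accuracy",
                                            "per_epoch_accuracy")),
                            names_to = "metric", values_to = "accuracy")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$p_removed, y = .data$accuracy,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "% most-uncertain epochs removed", y = "accuracy (%)",
                  colour = NULL,
                  title = sprintf("Selective prediction (%s voting)",
                                  attr(object, "scheme") %||% "")) +
    ggplot2::theme_minimal()
}

#' Plot a per-band performance report
#'
#' Grouped bars of the three per-band aggregates: best single fold, best
#' run mean, and overall mean.
#'
#' @param object A `band_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.band_report <- function(object, ...) {
  df <- tidyr::pivot_longer(as_tibble(object),
                            dplyr::all_of(c("best_fold", "best_run_mean",
                                            "overall_mean")),
                            names_to = "aggregate", values_to = "accuracy")
  df$band <- factor(df$band, levels = band_names())
  df$aggregate <- factor(df$aggregate,
                         levels = c("best_fold", "best_run_mean", "overall_mean"))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$accuracy,
                                   fill = .data$aggregate)) +
    ggplot2::geom_col(position = ggplot2::position_dodge()) +
    ggplot2::labs(x = NULL, y = "per-subject accuracy (%)", fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a training history
#'
#' @param object An `eeg_trained_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.eeg_trained_model <- function(object, ...) {
  df <- tidyr::pivot_longer(object$history,
                            dplyr::all_of(c("train_loss", "val_loss")),
                            names_to = "set", values_to = "loss")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$loss,
                                   colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_iteration, linetype = 2) +
    ggplot2::labs(colour = NULL) +
    ggplot2::theme_minimal()
}
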