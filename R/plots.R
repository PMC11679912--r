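#' Plot a predicted-MAE profile along the craniocaudal axis
#'
#' Step plot of the predicted per-slice MAE (and the ground-truth MAE when
#' available) against the axial slice index — a flat 2D stand-in for the
#' colour-mapped pMAE overlay a viewer would render.
#'
#' @param object a `pmae_prediction` from [predict_volume()].
#' @param mae_gt optional numeric vector of ground-truth slice MAEs.
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot pmae_prediction
#' @export
autoplot.pmae_prediction <- function(object, mae_gt = NULL, ...) {
  df <- object$records
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$slice_index,
                                        y = .data$mae_predicted)) +
    ggplot2::geom_step(linewidth = 0.6, colour = "#2166ac") +
    ggplot2::labs(x = "axial slice", y = "MAE (HU)",
                  title = "Predicted per-slice MAE") +
    ggplot2::theme_minimal()
  if (!is.null(mae_gt)) {
    stopifnot(length(mae_gt) == nrow(df))
    p <- p + ggplot2::geom_step(
      data = tibble::tibble(slice_index = df$slice_index, mae = mae_gt),
      ggplot2::aes(y = .data$mae), colour = "grey40", linetype = 2
    )
  }
  p
}

#' Plot PD and APD distributions per experiment
#'
#' @param object an `sctqc_eval` from [run_experiment_matrix()].
#' @param ... unused.
#' @return A ggplot object (box plots of PD and APD faceted by metric).
#' @method autoplot sctqc_eval
#' @export
autoplot.sctqc_eval <- function(object, ...) {
  long <- tidyr::pivot_longer(object$records, c("pd", "apd"),
                              names_to = "metric", values_to = "deviation")
  long$metric <- factor(toupper(long$metric), levels = c("PD", "APD"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$experiment,
                                     y = .data$deviation)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, fill = "#d1e5f0") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "deviation (HU)",
                  title = "Prediction deviation by experiment") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Plot a training log
#'
#' @param est an `estimator` with a training `log`.
#' @return A ggplot of training loss and validation metric per epoch.
#' @export
plot_training_log <- function(est) {
  stopifnot(inherits(est, "estimator"), !is.null(est$log))
  long <- tidyr::pivot_longer(est$log, c("train_loss", "val_metric"),
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, scales = "free_y") +
    ggplot2::labs(title = sprintf("%s training (best epoch %d)", est$task,
                                  est$best_epoch)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
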