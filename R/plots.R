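#' Plot training history
#'
#' Loss and accuracy per epoch for training and validation.
#'
#' @param object an `fmri_cnn_fit`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.fmri_cnn_fit <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history,
                           cols = c("train_loss", "val_loss",
                                    "train_accuracy", "val_accuracy"),
                           names_to = c("split", "metric"), names_sep = "_")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_epoch, linetype = "dashed",
                        colour = "grey50") +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = NULL, colour = NULL,
                  title = "Decoder training history",
                  subtitle = "dashed line: best validation-loss epoch") +
    ggplot2::theme_minimal()
}

#' Plot a one-vs-rest ROC curve
#'
#' @param object a `roc_curve`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.roc_curve <- function(object, ...) {
  ggplot2::ggplot(object$points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dotted",
                         colour = "grey60") +
    ggplot2::geom_step() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "1 - specificity", y = "sensitivity",
                  title = sprintf("ROC: %s (AUC %.3f)", object$target_label,
                                  object$auc)) +
    ggplot2::theme_minimal()
}

#' Plot a row-normalized confusion matrix
#'
#' @param object a `confusion_matrix`.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.confusion_matrix <- function(object, ...) {
  nm <- normalize_confusion(object)
  df <- tibble::as_tibble(as.table(nm), .name_repair = "minimal")
  names(df) <- c("truth", "predicted", "proportion")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$proportion)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(
      label = sprintf("%.2f", .data$proportion)), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue",
                                 limits = c(0, 1)) +
    ggplot2::scale_y_discrete(limits = rev(rownames(object))) +
    ggplot2::labs(title = "Confusion matrix (row-normalized)") +
    ggplot2::theme_minimal()
}

#' Plot axial slices of a 3D effect or pattern map
#'
#' @param object a `group_effect_map` or `pattern_map3d`.
#' @param slices z indices to show; defaults to an evenly spaced selection.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.group_effect_map <- function(object, slices = NULL, ...) {
  d <- dim(object)
  if (is.null(slices)) {
    slices <- unique(round(seq(1, d[3], length.out = min(6, d[3]))))
  }
  df <- purrr::map_dfr(slices, function(z) {
    g <- expand.grid(x = seq_len(d[1]), y = seq_len(d[2]))
    g$value <- as.numeric(object[, , z])
    g$slice <- sprintf("z = %d", z)
    g
  })
  lim <- max(abs(df$value), 1e-12)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_wrap(~slice) +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  limits = c(-lim, lim)) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "Voxelwise effect map", fill = "d") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.group_effect_map
#' @export
autoplot.pattern_map3d <- autoplot.group_effect_map

#' Plot a learning curve
#'
#' @param curve tibble from [learning_curve()].
#' @return A ggplot object.
#' @export
plot_learning_curve <- function(curve) {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$n_subjects,
                                      y = .data$test_accuracy)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10(breaks = curve$n_subjects) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "training subjects", y = "held-out accuracy",
                  title = "Decoder learning curve") +
    ggplot2::theme_minimal()
}
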