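#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a cross-validation result into per-class metrics
#'
#' @param x A `cv_result` from [cross_validate()].
#' @param ... Unused.
#' @return A tibble with one row per class: `class`, `support`, `recall`,
#'   `precision`, `f1`.
#' @export
tidy.cv_result <- function(x, ...) x$metrics$per_class

#' One-row summary of a cross-validation result
#'
#' @param x A `cv_result`.
#' @param ... Unused.
#' @return A one-row tibble: `k`, `n`, `accuracy`, `recall`, `precision`,
#'   `f1` (macro averages).
#' @export
glance.cv_result <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(k = x$eval_config$k, n = sum(x$confusion)),
    x$metrics$macro
  )
}

#' @rdname tidy.cv_result
#' @export
tidy.metric_report <- function(x, ...) x$per_class

#' @rdname glance.cv_result
#' @export
glance.metric_report <- function(x, ...) x$macro

#' Per-epoch training history of a fitted classifier
#'
#' @param x A `positioning_model`.
#' @param ... Unused.
#' @return The history tibble (`epoch`, mean batch `loss`).
#' @export
tidy.positioning_model <- function(x, ...) x$history

#' One-row summary of a fitted classifier
#'
#' @param x A `positioning_model`.
#' @param ... Unused.
#' @export
glance.positioning_model <- function(x, ...) {
  n_par <- sum(vapply(x$weights, length, 0L))
  tibble::tibble(backbone = x$cfg$backbone, n_parameters = n_par,
                 epochs = x$epochs_trained,
                 updates_per_epoch = x$updates_per_epoch,
                 final_loss = if (nrow(x$history)) x$history$loss[nrow(x$history)] else NA_real_,
                 train_accuracy = x$train_accuracy %||% NA_real_)
}

#' Turn a roi_detection into a one-row tibble
#'
#' @param x A `roi_detection`.
#' @param ... Unused.
#' @export
tidy.roi_detection <- function(x, ...) {
  tibble::tibble(
    part = x$part, row0 = x$box$row0, col0 = x$box$col0,
    height = x$box$height, width = x$box$width,
    foreground_fraction = x$foreground_fraction, converged = x$converged,
    extremum_row = if (is.null(x$extremum)) NA_integer_ else x$extremum$row,
    extremum_col = if (is.null(x$extremum)) NA_integer_ else x$extremum$col
  )
}

raster_df <- function(img) {
  tibble::tibble(
    row = rep(seq_len(nrow(img)), times = ncol(img)),
    col = rep(seq_len(ncol(img)), each = nrow(img)),
    intensity = as.numeric(img)
  )
}

#' Plot an image with a detected ROI overlaid
#'
#' @param img Standardized image matrix.
#' @param detection A `roi_detection` for that image.
#' @param downsample Integer factor to thin the raster for display speed.
#' @return A ggplot object (grayscale raster, ROI rectangle, extremum
#'   point if available).
#' @export
plot_detection <- function(img, detection, downsample = 4L) {
  assert_image_matrix(img)
  small <- img[seq(1, nrow(img), by = downsample),
               seq(1, ncol(img), by = downsample), drop = FALSE]
  df <- raster_df(small)
  df$row <- (df$row - 1) * downsample + 1
  df$col <- (df$col - 1) * downsample + 1
  b <- detection$box
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::annotate("rect", xmin = b$col0, xmax = b$col0 + b$width - 1,
                      ymin = b$row0, ymax = b$row0 + b$height - 1,
                      colour = "red", fill = NA, linewidth = 0.6) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s detection (converged = %s)",
                                  detection$part, detection$converged),
                  x = NULL, y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(detection$extremum)) {
    p <- p + ggplot2::annotate("point", x = detection$extremum$col,
                               y = detection$extremum$row,
                               colour = "cyan", size = 2)
  }
  p
}

#' Plot a detected patch
#'
#' @param object A `roi_detection`.
#' @param ... Unused.
#' @export
autoplot.roi_detection <- function(object, ...) {
  df <- raster_df(object$patch)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s patch", object$part), x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Confusion-matrix heatmap for a cross-validation result
#'
#' @param object A `cv_result`.
#' @param ... Unused.
#' @export
autoplot.cv_result <- function(object, ...) {
  cm <- unclass(object$confusion)
  df <- tibble::tibble(
    truth = factor(rep(rownames(cm), times = 3), levels = label_names),
    predicted = factor(rep(colnames(cm), each = 3), levels = label_names),
    n = as.vector(cm)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_gradient(low = "grey20", high = "steelblue") +
    ggplot2::scale_y_discrete(limits = rev(label_names)) +
    ggplot2::labs(title = "Summed cross-validation confusion matrix",
                  x = "predicted", y = "truth") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
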