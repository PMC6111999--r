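#' @importFrom generics tidy glance
#' @importFrom ggplot2 autoplot
NULL

#' @export
generics::tidy

#' @export
generics::glance

#' @export
ggplot2::autoplot

#' Tidy a trained classifier
#'
#' One row per layer with its type, output shape and parameter count.
#'
#' @param x a `cnn_model`.
#' @param ... unused.
#' @return A tibble.
#' @export
tidy.cnn_model <- function(x, ...) {
  purrr::imap_dfr(x$layers, function(l, li) {
    tibble(layer = li, type = l$type,
           out_shape = paste(l$out_shape, collapse = "x"),
           n_parameters = if (is.null(l$weights)) 0L else length(l$weights),
           trainable = isTRUE(l$trainable))
  })
}

#' @rdname tidy.cnn_model
#' @export
glance.cnn_model <- function(x, ...) {
  tibble(
    n_layers = length(x$layers),
    n_parameters = sum(vapply(x$layers, function(l)
      if (is.null(l$weights)) 0L else length(l$weights), integer(1))),
    trained = isTRUE(x$trained),
    epochs = if (is.null(x$history)) NA_integer_ else nrow(x$history),
    final_loss = if (is.null(x$history)) NA_real_ else
      x$history$loss[nrow(x$history)]
  )
}

#' @rdname tidy.cnn_model
#' @param object a trained `cnn_model` with a loss history.
#' @export
autoplot.cnn_model <- function(object, ...) {
  if (is.null(object$history)) stop_state("model has no training history")
  ggplot2::ggplot(object$history, ggplot2::aes(x = .data$epoch, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "mean batch loss",
                  title = "Training loss") +
    ggplot2::theme_minimal()
}

#' Tidy evaluation results
#'
#' `tidy()` returns the quality measures in long form, `glance()` a single
#' wide row including the confusion counts, and `autoplot()` a confusion
#' matrix heat map.
#'
#' @param x,object a `dermo_eval` from [evaluate_predictions()].
#' @param ... unused.
#' @return A tibble (`tidy`, `glance`) or a ggplot (`autoplot`).
#' @export
tidy.dermo_eval <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' @rdname tidy.dermo_eval
#' @export
glance.dermo_eval <- function(x, ...) {
  dplyr::bind_cols(tibble(TP = x$counts[["TP"]], TN = x$counts[["TN"]],
                          FP = x$counts[["FP"]], FN = x$counts[["FN"]]),
                   x$metrics)
}

#' @rdname tidy.dermo_eval
#' @export
autoplot.dermo_eval <- function(object, ...) {
  cc <- object$counts
  df <- tibble(
    truth = c("positive", "negative", "positive", "negative"),
    predicted = c("positive", "positive", "negative", "negative"),
    count = c(cc[["TP"]], cc[["FP"]], cc[["FN"]], cc[["TN"]])
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$predicted, y = .data$truth,
                                   fill = .data$count)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$count), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(title = paste0("Confusion matrix (positive = ",
                                 object$positive_class, ")")) +
    ggplot2::theme_minimal()
}

image_to_df <- function(img) {
  h <- dim(img)[1]; w <- dim(img)[2]
  tibble(
    x = rep(seq_len(w), each = h),
    y = rep(seq_len(h), times = w),
    fill = grDevices::rgb(img[, , 1] / 255, img[, , 2] / 255, img[, , 3] / 255)
  )
}

#' Plot key points over an image
#'
#' @param img RGB array.
#' @param kps key-point tibble.
#' @return A ggplot.
#' @export
plot_keypoints <- function(img, kps) {
  ggplot2::ggplot(image_to_df(img), ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::geom_point(data = kps, ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "red", shape = 1,
                        size = 2, inherit.aes = FALSE) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' Plot a synthetic scene with its ground truth
#'
#' Shows the rendered frame with nevus bounding boxes (red: suspicious,
#' blue: benign).
#'
#' @param object a `scene_truth`.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.scene_truth <- function(object, ...) {
  boxes <- purrr::map_dfr(object$nevi, function(sp) {
    r <- sp$diameter_mm * sp$px_per_mm / 2
    tibble(xmin = sp$center[1] - r, xmax = sp$center[1] + r,
           ymin = sp$center[2] - r, ymax = sp$center[2] + r,
           label = sp$label)
  })
  p <- ggplot2::ggplot(image_to_df(object$image),
                       ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
  if (nrow(boxes) > 0)
    p <- p + ggplot2::geom_rect(
      data = boxes,
      ggplot2::aes(xmin = .data$xmin, xmax = .data$xmax,
                   ymin = .data$ymin, ymax = .data$ymax,
                   colour = .data$label),
      fill = NA, inherit.aes = FALSE) +
      ggplot2::scale_colour_manual(values = c(benign = "blue",
                                              suspicious = "red"))
  p
}
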