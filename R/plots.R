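# ggplot2 displays for the result objects.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an RGB image tibble-free
#'
#' Renders an H x W x 3 array with ggplot2 (one tile per pixel at reduced
#' resolution for speed).
#'
#' @param image H x W x 3 array in [0, 1].
#' @param max_px Downsample so the longer side is at most this many pixels.
#' @return A ggplot object.
#' @export
plot_image <- function(image, max_px = 256) {
  stopifnot_image(image)
  while (max(dim(image)[1:2]) > max_px) {
    image <- array(c(downsample2(image[, , 1]), downsample2(image[, , 2]),
                     downsample2(image[, , 3])),
                   c(dim(downsample2(image[, , 1])), 3))
  }
  d <- dim(image)
  df <- tidyr::expand_grid(y = seq_len(d[1]), x = seq_len(d[2]))
  df$fill <- grDevices::rgb(image[, , 1], image[, , 2], image[, , 3])
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed(expand = FALSE) +
    ggplot2::theme_void()
}

#' @exportS3Method ggplot2::autoplot
autoplot.col6_confusion <- function(object, ...) {
  m <- unclass(object)
  labs <- rownames(m) %||% as.character(seq_len(nrow(m)))
  df <- tidyr::expand_grid(true = labs, pred = labs)
  df$count <- as.vector(t(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$pred, .data$true)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$count), color = "grey40") +
    ggplot2::geom_text(ggplot2::aes(label = .data$count)) +
    ggplot2::scale_fill_gradient(low = "white", high = "#2c7bb6") +
    ggplot2::scale_y_discrete(limits = rev(labs)) +
    ggplot2::labs(x = "predicted", y = "true") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.col6_fedavg <- function(object, ...) {
  h <- object$history
  ggplot2::ggplot(h, ggplot2::aes(.data$round)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$local_loss,
                                    color = .data$site_id)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$global_loss),
                       linewidth = 1, color = "black") +
    ggplot2::labs(y = "regularized loss", color = "node",
                  title = "FedAvg training (black: weighted global loss)") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.col6_comparison <- function(object, metric = c("f1", "accuracy"),
                                     ...) {
  metric <- match.arg(metric)
  s <- object$summary
  s$mean <- if (metric == "f1") s$mean_f1 else s$mean_accuracy
  s$std <- if (metric == "f1") s$std_f1 else s$std_accuracy
  ggplot2::ggplot(s, ggplot2::aes(.data$arm, .data$mean)) +
    ggplot2::geom_col(fill = "#74add1") +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$std,
                                        ymax = .data$mean + .data$std),
                           width = 0.2) +
    ggplot2::labs(y = if (metric == "f1") "macro-F1 (mean ± SD)"
                  else "accuracy (mean ± SD)", x = NULL) +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
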