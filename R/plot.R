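#' Plot a plant skeleton
#'
#' Draws the traced polylines (coloured by leaf), leaf tips, and the pot
#' circle or reference line, in image coordinates (y axis reversed so the
#' plot matches the image).
#'
#' @param object A `plant_skeleton`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plant_skeleton <- function(object, ...) {
  df <- object$leaves
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                        group = .data$leaf_id,
                                        colour = factor(.data$leaf_id))) +
    ggplot2::geom_path(linewidth = 0.6) +
    ggplot2::geom_point(data = dplyr::filter(df, .data$vertex == 1L),
                        size = 2, shape = 17) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(colour = "leaf", x = "x (px)", y = "y (px)",
                  title = sprintf("%s-view skeleton, %d leaves",
                                  object$view, leaf_count(object)))
  if (!is.null(object$pot)) {
    th <- seq(0, 2 * pi, length.out = 181)
    circ <- tibble(x = object$pot$center[[1L]] + object$pot$radius * cos(th),
                   y = object$pot$center[[2L]] + object$pot$radius * sin(th))
    p <- p + ggplot2::geom_path(data = circ,
                                ggplot2::aes(.data$x, .data$y),
                                inherit.aes = FALSE, linetype = 2,
                                colour = "grey40")
  }
  if (!is.null(object$reference)) {
    p <- p + ggplot2::geom_hline(yintercept = object$reference$row,
                                 linetype = 2, colour = "grey40")
  }
  p
}

#' Plot sampled seed points
#'
#' @param object A `seed_points` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.seed_points <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y,
                                       colour = .data$visited)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' Plot a binary mask
#'
#' @param mask Logical matrix.
#' @return A ggplot raster of the mask.
#' @export
plot_mask <- function(mask) {
  df <- tidyr::expand_grid(y = seq_len(nrow(mask)), x = seq_len(ncol(mask)))
  df$fg <- as.vector(t(mask))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$fg)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "black",
                                          `TRUE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "x (px)", y = "y (px)")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
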