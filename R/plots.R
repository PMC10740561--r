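# ggplot2 views of plans and simulated read-outs.

#' Plot a hit list
#'
#' Scatter of hit coordinates in physical um, coloured by region, with an
#' optional target-mask outline underneath -- the planning-side analogue of an
#' etched-film micrograph.
#'
#' @param hits A `hitlist`.
#' @param mask Optional target mask tibble drawn as a background raster.
#' @param grid Required when `mask` is given.
#' @param size Point size.
#' @return A ggplot object.
#' @export
plot_hits <- function(hits, mask = NULL, grid = NULL, size = 0.3) {
  p <- ggplot2::ggplot()
  if (!is.null(mask)) {
    stopifnot(!is.null(grid))
    md <- tibble::tibble(x = (mask$col + 0.5) * grid$scale,
                         y = (mask$row + 0.5) * grid$scale)
    p <- p + ggplot2::geom_tile(
      data = md, ggplot2::aes(x = .data$x, y = .data$y),
      width = grid$scale, height = grid$scale, fill = "grey85"
    )
  }
  p +
    ggplot2::geom_point(
      data = tibble::as_tibble(hits),
      ggplot2::aes(x = .data$x_um, y = .data$y_um, colour = .data$region),
      size = size
    ) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "region") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.hitlist <- function(object, ...) plot_hits(object, ...)

#' @export
autoplot.pit_image <- function(object, ...) {
  scale <- attr(object, "scale")
  idx <- which(object, arr.ind = TRUE)
  df <- tibble::tibble(x = (idx[, 2] - 0.5) * scale, y = (idx[, 1] - 0.5) * scale)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_tile(width = scale, height = scale, fill = "black") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)",
                  title = sprintf("simulated etch pits (pit %.3g um)",
                                  attr(object, "pit_um"))) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.uniformity_report <- function(object, ...) {
  ggplot2::ggplot(object$counts, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_bar() +
    ggplot2::labs(
      x = "hits per quadrat", y = "quadrats",
      title = sprintf("dispersion index %.3g (%d cells, %d hits)",
                      object$dispersion, object$n_cells, object$n_hits)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.dose_map <- function(object, ...) {
  b <- attr(object, "block_um")
  o <- attr(object, "origin_um")
  idx <- which(object > 0, arr.ind = TRUE)
  df <- tibble::tibble(
    x = o[1] + (idx[, 2] - 0.5) * b,
    y = o[2] + (idx[, 1] - 0.5) * b,
    dose = object[idx]
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$dose)) +
    ggplot2::geom_tile(width = b, height = b) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "Gy") +
    ggplot2::theme_minimal()
}
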