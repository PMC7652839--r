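# ggplot2 visualisation of results.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a segmentation result over its source image
#'
#' @param object An `lcpm_result`.
#' @param image Optional source image matrix to show under the contour.
#' @param ... Unused.
#' @return A ggplot object (image raster, contour path, window centres).
#' @method autoplot lcpm_result
#' @export
autoplot.lcpm_result <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    df <- data.frame(row = as.vector(row(image)), col = as.vector(col(image)),
                     value = as.vector(unclass(image)))
    p <- p + ggplot2::geom_raster(data = df,
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$value)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white", guide = "none")
  }
  p +
    ggplot2::geom_path(data = object$contour,
                       ggplot2::aes(x = .data$col, y = .data$row),
                       colour = "magenta", linewidth = 0.8) +
    ggplot2::geom_point(data = object$windows,
                        ggplot2::aes(x = .data$center_col, y = .data$center_row),
                        shape = 3, colour = "cyan", size = 1.5) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s contour, %d windows",
                                  if (object$closed) "closed" else "open",
                                  nrow(object$windows)))
}

#' Plot a thickness field
#'
#' @param object A `thickness_field` from [thickness_map()].
#' @param ... Unused.
#' @return A ggplot raster of plate heights (grooves dark).
#' @method autoplot thickness_field
#' @export
autoplot.thickness_field <- function(object, ...) {
  df <- data.frame(row = as.vector(row(object)), col = as.vector(col(object)),
                   h = as.vector(unclass(object)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$h)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "h") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, title = "plate thickness")
}

#' Plot a crack path over its thickness field
#'
#' @param crack A `crack_path`.
#' @param thickness Optional thickness matrix for context.
#' @return A ggplot object.
#' @export
plot_crack <- function(crack, thickness = NULL) {
  stopifnot(inherits(crack, "crack_path"))
  p <- if (!is.null(thickness)) autoplot.thickness_field(thickness) else
    ggplot2::ggplot() + ggplot2::scale_y_reverse() + ggplot2::coord_fixed()
  p + ggplot2::geom_path(
    data = data.frame(row = crack$vertices[, 1], col = crack$vertices[, 2]),
    ggplot2::aes(x = .data$col, y = .data$row),
    colour = "red", linewidth = 0.9, inherit.aes = FALSE)
}

#' @importFrom rlang .data
NULL
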