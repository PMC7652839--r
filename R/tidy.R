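# broom-style accessors for run results.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a segmentation result
#'
#' @param x An `lcpm_result`.
#' @param ... Unused.
#' @return The contour as a tibble (`row`, `col`, `window`), one row per
#'   contour point; bridge points carry `window = NA`.
#' @method tidy lcpm_result
#' @export
tidy.lcpm_result <- function(x, ...) {
  tibble::as_tibble(x$contour)
}

#' One-row summary of a segmentation result
#'
#' @param x An `lcpm_result`.
#' @param ... Unused.
#' @return Tibble with `closed`, `n_points`, `n_windows`, `fronts`,
#'   `stalls`, `perimeter` (polyline length, px) and `area` (mask area, px^2).
#' @method glance lcpm_result
#' @export
glance.lcpm_result <- function(x, ...) {
  d <- sqrt(diff(x$contour$row)^2 + diff(x$contour$col)^2)
  tibble::tibble(closed = x$closed,
                 n_points = nrow(x$contour),
                 n_windows = nrow(x$windows),
                 fronts = x$fronts,
                 stalls = x$stalls,
                 perimeter = sum(d),
                 area = sum(x$mask))
}
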