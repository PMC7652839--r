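# Local windows and the image -> plate-thickness map.

#' Specify a local square window
#'
#' A window is the Chebyshev ball of radius `half_size` around `center`:
#' the (2L+1) x (2L+1) pixel block on which one local plate model is built.
#'
#' @param center Length-2 numeric `(row, col)` pixel coordinate of the window
#'   center in the full image.
#' @param half_size Window half-size L in pixels (>= 4).
#' @return A `window_spec` list with elements `center` and `half_size`.
#' @export
window_spec <- function(center, half_size) {
  if (length(center) != 2 || !all(is.finite(center)))
    stop_input("`center` must be a finite (row, col) pair")
  check_scalar(half_size, "half_size")
  if (half_size < 4) stop_param("`half_size` must be >= 4")
  structure(list(center = round(as.numeric(center)), half_size = as.integer(round(half_size))),
            class = "window_spec")
}

#' Extract a local window from an image
#'
#' Returns the pixels with `max(|row - r0|, |col - c0|) <= L`. Windows that
#' would extend past the image border are clamped to it (not mirrored:
#' mirrored intensities would fabricate spurious grooves) and the clamp is
#' recorded in the `clamped` attribute.
#'
#' @param image Numeric matrix (any of the image classes).
#' @param spec A [window_spec()].
#' @return Matrix of window pixels with attributes `rows`, `cols` (the global
#'   pixel indices covered) and `clamped`.
#' @export
extract_window <- function(image, spec) {
  stopifnot(inherits(spec, "window_spec"))
  if (!is.matrix(image)) stop_input("`image` must be a matrix")
  r0 <- spec$center[1]; c0 <- spec$center[2]; L <- spec$half_size
  if (r0 < 1 || r0 > nrow(image) || c0 < 1 || c0 > ncol(image))
    stop_input("window center lies outside the image")
  rows <- (r0 - L):(r0 + L); cols <- (c0 - L):(c0 + L)
  rk <- rows[rows >= 1 & rows <= nrow(image)]
  ck <- cols[cols >= 1 & cols <= ncol(image)]
  clamped <- length(rk) < length(rows) || length(ck) < length(cols)
  out <- unclass(image)[rk, ck, drop = FALSE]
  attributes(out) <- c(attributes(out)["dim"],
                       list(rows = rk, cols = ck, clamped = clamped))
  out
}

#' Map window intensities to plate thickness
#'
#' Linearly maps the enhanced intensities of a window onto plate heights in
#' `[1, H]`: the window minimum (the groove bottom, i.e. the boundary) gets
#' thickness exactly 1 and the maximum exactly `H`. A constant window has no
#' groove; it is returned as uniform thickness `H` with
#' `degenerate = TRUE`, which the driver treats as a boundary gap.
#'
#' @param window Numeric matrix of enhanced intensities.
#' @param H Maximum plate thickness (>= 2), in pixel units.
#' @return A `thickness_field`: matrix of heights with attributes `H` and
#'   `degenerate`.
#' @export
thickness_map <- function(window, H) {
  if (!is.matrix(window) || length(window) == 0)
    stop_input("`window` must be a non-empty numeric matrix")
  check_scalar(H, "H")
  if (H < 2) stop_param("`H` must be >= 2")
  lo <- min(window); hi <- max(window)
  if (hi == lo) {
    h <- matrix(H, nrow(window), ncol(window))
    degen <- TRUE
  } else {
    h <- (window - lo) * (H - 1) / (hi - lo) + 1
    degen <- FALSE
  }
  structure(h, H = H, degenerate = degen,
            class = c("thickness_field", "matrix", "array"))
}
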