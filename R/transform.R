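# Intensity transforms: grayscale image -> contrast-enhanced gradient field.
#
# The plate geometry is built from the gradient magnitude of the
# Gaussian-smoothed image: boundaries have high gradient, a negative rescale
# flips them to LOW values, and a power-law (gamma) transform deepens the
# contrast so that the thickness map carves a pronounced groove at the edge.

#' Construct a grayscale image
#'
#' Wraps a numeric matrix as a grayscale image with values rescaled to
#' \[0, 1\]. Rows index the vertical image axis (top to bottom), columns the
#' horizontal axis, matching R's matrix convention for raster images.
#'
#' @param pixels Numeric matrix of intensities. Values outside \[0, 1\] are
#'   linearly rescaled to that range.
#' @param pixel_spacing Physical size of one pixel (e.g. mm). Used only to
#'   scale reported distances; defaults to 1.
#' @return A `gray_image`: the pixel matrix with a `pixel_spacing` attribute.
#' @export
gray_image <- function(pixels, pixel_spacing = 1) {
  check_image(pixels, "pixels")
  check_scalar(pixel_spacing, "pixel_spacing")
  rng <- range(pixels)
  if (rng[1] < 0 || rng[2] > 1) {
    pixels <- if (rng[2] > rng[1]) (pixels - rng[1]) / (rng[2] - rng[1]) else pixels * 0
  }
  structure(pixels, pixel_spacing = pixel_spacing, class = c("gray_image", "matrix", "array"))
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d, range [%.3f, %.3f], pixel spacing %g\n",
              nrow(x), ncol(x), min(x), max(x), attr(x, "pixel_spacing") %||% 1))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# --- convolution machinery (reflect padding, separable kernels) ------------

pad_reflect <- function(x, r) {
  nr <- nrow(x); nc <- ncol(x)
  ri <- c(rev(seq_len(min(r, nr))), seq_len(nr), nr + 1 - seq_len(min(r, nr)))
  ci <- c(rev(seq_len(min(r, nc))), seq_len(nc), nc + 1 - seq_len(min(r, nc)))
  x[ri, ci, drop = FALSE]
}

# Correlate columns of `x` with kernel `k` (odd length), valid region only.
corr_cols <- function(x, k) {
  r <- (length(k) - 1L) / 2L
  n <- nrow(x) - 2L * r
  out <- matrix(0, n, ncol(x))
  for (t in seq_along(k)) {
    if (k[t] != 0) out <- out + k[t] * x[seq_len(n) + (t - 1L), , drop = FALSE]
  }
  out
}

# Separable correlation with reflect padding; k_row runs down columns
# (vertical axis), k_col across rows.
conv_sep <- function(x, k_row, k_col) {
  r <- max((length(k_row) - 1L) / 2L, (length(k_col) - 1L) / 2L)
  xp <- pad_reflect(x, r)
  pr <- (length(k_row) - 1L) / 2L
  pc <- (length(k_col) - 1L) / 2L
  # trim the padding not consumed by each kernel
  y <- corr_cols(xp[(r - pr + 1L):(nrow(xp) - r + pr), , drop = FALSE], k_row)
  y <- t(corr_cols(t(y[, (r - pc + 1L):(ncol(xp) - r + pc), drop = FALSE]), k_col))
  y
}

gaussian_kernel <- function(sigma, truncate = 4) {
  r <- max(1L, ceiling(truncate * sigma))
  g <- exp(-0.5 * ((-r:r) / sigma)^2)
  g / sum(g)
}

central_diff_kernel <- function() c(-0.5, 0, 0.5)

# Discrete derivative-of-Gaussian: central difference of the sampled Gaussian.
dog_kernel <- function(sigma, truncate = 4) {
  g <- gaussian_kernel(sigma, truncate)
  gp <- c(0, 0, g, 0, 0)
  # central difference of the sampled Gaussian; keep the full support so the
  # two convolution orderings agree to round-off (associativity)
  (gp[3:length(gp)] - gp[1:(length(gp) - 2)]) / 2
}

#' Gaussian-gradient magnitude of an image
#'
#' Computes the squared gradient magnitude of the Gaussian-smoothed image,
#' the field whose large values mark intensity boundaries. Two equivalent
#' orderings are provided: `"dog"` convolves the image directly with
#' derivative-of-Gaussian kernels (the fast form), while `"smooth_diff"`
#' smooths first and then applies a central difference. By convolution
#' associativity the two agree away from the image border.
#'
#' @param image Numeric matrix (or `gray_image`), at least 3x3.
#' @param sigma Gaussian standard deviation in pixels (> 0).
#' @param method `"dog"` (default) or `"smooth_diff"`.
#' @param squared If `TRUE` (default) return `|grad|^2`, else `|grad|`. The
#'   downstream rescale normalises either choice.
#' @return A `gradient_image`: nonnegative matrix of the same shape with
#'   attributes `sigma` and `squared`.
#' @export
gaussian_gradient <- function(image, sigma,
                              method = c("dog", "smooth_diff"),
                              squared = TRUE) {
  method <- match.arg(method)
  check_scalar(sigma, "sigma")
  check_image(image, "image")
  x <- unclass(image)
  attributes(x) <- attributes(x)["dim"]
  g <- gaussian_kernel(sigma)
  if (method == "dog") {
    d <- dog_kernel(sigma)
    gr <- conv_sep(x, d, g)   # derivative along rows (vertical)
    gc <- conv_sep(x, g, d)   # derivative along cols (horizontal)
  } else {
    s <- conv_sep(x, g, g)
    d <- central_diff_kernel()
    gr <- conv_sep(s, d, c(1))
    gc <- conv_sep(s, c(1), d)
  }
  m <- gr^2 + gc^2
  if (!squared) m <- sqrt(m)
  structure(m, sigma = sigma, squared = squared,
            class = c("gradient_image", "matrix", "array"))
}

# Internal: the two directional Gaussian-derivative components (unsquared).
gradient_components <- function(image, sigma) {
  x <- unclass(image)
  attributes(x) <- attributes(x)["dim"]
  g <- gaussian_kernel(sigma)
  d <- dog_kernel(sigma)
  list(dr = conv_sep(x, d, g), dc = conv_sep(x, g, d))
}

#' Negative rescale of a gradient field
#'
#' Affinely maps a nonnegative field to \[0, 1\] and inverts it, so that the
#' global maximum (the strongest edge) maps to 0 and the global minimum to 1.
#' Boundaries become the LOW values that the thickness map later turns into
#' grooves.
#'
#' A constant input carries no boundary information; it is returned as
#' all-ones with attribute `degenerate = TRUE`, which the window driver
#' treats as a boundary gap rather than an error.
#'
#' @param gradient Nonnegative numeric matrix.
#' @return Matrix in \[0, 1\] with attribute `degenerate`.
#' @export
negative_rescale <- function(gradient) {
  if (!is.matrix(gradient) || length(gradient) == 0)
    stop_input("`gradient` must be a non-empty numeric matrix")
  lo <- min(gradient); hi <- max(gradient)
  if (hi == lo) {
    out <- matrix(1, nrow(gradient), ncol(gradient))
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  out <- 1 - (gradient - lo) / (hi - lo)
  attr(out, "degenerate") <- FALSE
  out
}

#' Power-law (gamma) contrast transform
#'
#' Raises every pixel of a \[0, 1\] image to the power `gamma`. For
#' `gamma > 1` high values are stretched apart and low values compressed
#' towards 0, which deepens the groove a boundary carves into the plate.
#' The map is monotone for any `gamma > 0` and fixes 0 and 1.
#'
#' @param image Numeric matrix with values in \[0, 1\].
#' @param gamma Positive exponent.
#' @return An `enhanced_image`: matrix in \[0, 1\] with attribute `gamma`
#'   (the `degenerate` attribute of the input, if any, is carried through).
#' @export
power_transform <- function(image, gamma) {
  check_scalar(gamma, "gamma")
  if (!is.matrix(image)) stop_input("`image` must be a numeric matrix")
  if (min(image) < -1e-12 || max(image) > 1 + 1e-12)
    stop_input("`image` values must lie in [0, 1]")
  out <- pmin(pmax(image, 0), 1)^gamma
  attr(out, "gamma") <- gamma
  attr(out, "degenerate") <- isTRUE(attr(image, "degenerate"))
  class(out) <- c("enhanced_image", "matrix", "array")
  out
}

#' Is a transform result degenerate (information-free)?
#'
#' @param x Result of [negative_rescale()], [power_transform()] or
#'   [thickness_map()].
#' @return `TRUE` if the source window was constant.
#' @export
is_degenerate <- function(x) isTRUE(attr(x, "degenerate"))

#' Full enhancement pipeline for one window or image
#'
#' Negative-rescales a gradient field and applies the gamma transform:
#' the composition used on each local window before thickness mapping.
#'
#' @param gradient Nonnegative matrix (a window of the gradient field).
#' @param gamma Positive exponent.
#' @return `enhanced_image` in \[0, 1\], low at boundaries.
#' @export
enhance_gradient <- function(gradient, gamma) {
  power_transform(negative_rescale(gradient), gamma)
}
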