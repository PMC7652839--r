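# Image and artifact I/O: PNG/TIFF grayscale in, mask PNG and contour JSON out.

#' Read a grayscale image
#'
#' Reads an 8- or 16-bit PNG or TIFF, normalised to \[0, 1\]. Colour images
#' are rejected (the method operates on scalar intensity).
#'
#' @param path File path; format chosen by extension (`.png`, `.tif`,
#'   `.tiff`).
#' @param pixel_spacing Physical pixel size to attach. Default 1.
#' @return A [gray_image()].
#' @export
read_gray <- function(path, pixel_spacing = 1) {
  if (!file.exists(path)) stop_input(sprintf("file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  x <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_input(sprintf("unsupported image format: .%s (use PNG or TIFF)", ext)))
  if (length(dim(x)) == 3) {
    if (dim(x)[3] == 2) x <- x[, , 1]                        # gray + alpha
    else if (all(x[, , 1] == x[, , 2]) && all(x[, , 2] == x[, , 3])) x <- x[, , 1]
    else stop_input("colour images are not supported; convert to grayscale")
  }
  gray_image(x, pixel_spacing = pixel_spacing)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Foreground (interior) pixels are written as 255, background as 0.
#'
#' @param mask Logical matrix.
#' @param path Output PNG path.
#' @return `path`, invisibly.
#' @export
write_mask_png <- function(mask, path) {
  png::writePNG(ifelse(mask, 1, 0), path)
  invisible(path)
}

#' Write a segmentation result as JSON
#'
#' Ordered `[row, col]` contour points, the `closed` flag, per-window
#' provenance indices, and the effective configuration echo: a complete
#' machine-readable record of the run.
#'
#' @param result An `lcpm_result` from [run_lcpm()].
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_contour_json <- function(result, path) {
  stopifnot(inherits(result, "lcpm_result"))
  cfg <- result$config
  obj <- list(
    points = unname(apply(cbind(result$contour$row, result$contour$col), 1,
                          function(p) c(p[1], p[2]), simplify = FALSE)),
    closed = result$closed,
    window = result$contour$window,
    n_windows = nrow(result$windows),
    fronts = result$fronts,
    stalls = result$stalls,
    dim = result$dim,
    config = list(L = cfg$L, alpha = cfg$alpha, H = cfg$H, sigma = cfg$sigma,
                  gamma = cfg$gamma, transform_scope = cfg$transform_scope,
                  gap_max = cfg$gap_max, merge_tol = cfg$merge_tol,
                  closure_eps = cfg$closure_eps, seed_len = cfg$seed_len))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Read an ordered list of image slices
#'
#' @param paths Character vector of image files, in stack order.
#' @param pixel_spacing Physical pixel size. Default 1.
#' @return List of [gray_image()] objects.
#' @export
read_stack <- function(paths, pixel_spacing = 1) {
  lapply(paths, read_gray, pixel_spacing = pixel_spacing)
}
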