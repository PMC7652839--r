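# Segmentation quality metrics: Dice overlap, Hausdorff boundary distance,
# true-negative / false-positive rates, plus contour rasterisation.

#' Dice similarity coefficient
#'
#' `2|A intersect B| / (|A| + |B|)` for two binary masks of the same shape.
#' Symmetric in its arguments; 1 exactly when the masks are identical and
#' non-empty. Two empty masks are treated as perfect agreement on absence
#' (returns 1 with a warning).
#'
#' @param pred,ref Logical (or 0/1 numeric) matrices of equal dimension.
#' @return Scalar in \[0, 1\].
#' @export
dice <- function(pred, ref) {
  pred <- as_mask(pred); ref <- as_mask(ref)
  if (!all(dim(pred) == dim(ref))) stop_input("masks must have the same shape")
  a <- sum(pred); b <- sum(ref)
  if (a + b == 0) {
    rlang::warn("both masks empty; Dice defined as 1")
    return(1)
  }
  2 * sum(pred & ref) / (a + b)
}

as_mask <- function(x) {
  if (!is.matrix(x)) stop_input("mask must be a matrix")
  if (is.logical(x)) x else x > 0.5
}

#' Hausdorff distance between point sets
#'
#' Symmetric worst-case nearest-neighbour distance
#' `max(sup_a inf_b d(a,b), sup_b inf_a d(a,b))` between two finite point
#' sets, in pixels, scaled by `spacing` if physical units are wanted. Masks
#' are reduced to their 8-connected outlines first; contours and matrices
#' are used as-is.
#'
#' @param pred,ref Two-column `(row, col)` matrices, `contour` tibbles, or
#'   logical masks.
#' @param spacing Physical size per pixel; default 1 (result in px).
#' @return Scalar distance.
#' @export
hausdorff <- function(pred, ref, spacing = 1) {
  A <- boundary_points(pred)
  B <- boundary_points(ref)
  if (nrow(A) == 0 || nrow(B) == 0) stop_input("empty point set")
  d1 <- max(nearest_dist(A, B))
  d2 <- max(nearest_dist(B, A))
  max(d1, d2) * spacing
}

boundary_points <- function(x) {
  if (is.logical(x)) return(mask_outline(x))
  if (is.data.frame(x)) return(cbind(x$row, x$col))
  x <- rbind(x)
  if (ncol(x) == 2) return(x)
  stop_input("cannot interpret boundary input")
}

#' 8-connected outline of a mask
#'
#' Mask pixels adjacent (8-connectivity) to background or to the image
#' edge.
#'
#' @param mask Logical matrix.
#' @return Two-column matrix of `(row, col)` outline pixel coordinates.
#' @export
mask_outline <- function(mask) {
  mask <- as_mask(mask)
  nr <- nrow(mask); nc <- ncol(mask)
  pad <- matrix(FALSE, nr + 2, nc + 2)
  pad[2:(nr + 1), 2:(nc + 1)] <- mask
  inner <- matrix(TRUE, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    inner <- inner & pad[2:(nr + 1) + dr, 2:(nc + 1) + dc]
  }
  which(mask & !inner, arr.ind = TRUE)
}

#' True-negative and false-positive rates
#'
#' `tnr = TN / (TN + FP)` and `fpr = FP / (FP + TN)` over the reference
#' background; they sum to 1 exactly. Quantifies boundary overflow: a
#' segmentation that leaks outside the reference raises the FPR.
#'
#' @param pred,ref Masks of equal shape; `ref` must have non-empty
#'   background.
#' @return Named list with `tnr` and `fpr`.
#' @export
tnr_fpr <- function(pred, ref) {
  pred <- as_mask(pred); ref <- as_mask(ref)
  if (!all(dim(pred) == dim(ref))) stop_input("masks must have the same shape")
  bg <- !ref
  if (!any(bg)) stop_input("reference has no background; rates undefined")
  tn <- sum(bg & !pred)
  fp <- sum(bg & pred)
  list(tnr = tn / (tn + fp), fpr = fp / (fp + tn))
}

#' All segmentation metrics at once
#'
#' @param pred,ref Masks of equal shape (logical or 0/1).
#' @param spacing Physical pixel size for the Hausdorff distance; default 1.
#' @return One-row tibble with `dsc`, `hausdorff`, `tnr`, `fpr`.
#' @export
seg_metrics <- function(pred, ref, spacing = 1) {
  tf <- tnr_fpr(pred, ref)
  tibble::tibble(dsc = dice(pred, ref),
                 hausdorff = hausdorff(as_mask(pred), as_mask(ref), spacing),
                 tnr = tf$tnr, fpr = tf$fpr)
}

#' Rasterise a closed contour to a binary mask
#'
#' Even-odd (crossing-count) polygon fill evaluated at pixel centres, by
#' horizontal scanlines; pixels under the contour polyline itself count as
#' interior.
#'
#' @param contour A `contour` tibble (or two-column `(row, col)` matrix).
#'   Open contours yield a mask of just the polyline pixels.
#' @param dim Output dimensions `c(rows, cols)`.
#' @return Logical matrix.
#' @export
contour_mask <- function(contour, dim) {
  pts <- if (is.data.frame(contour)) cbind(contour$row, contour$col) else rbind(contour)
  closed <- isTRUE(attr(contour, "closed"))
  mask <- matrix(FALSE, dim[1], dim[2])
  if (nrow(pts) < 2) return(mask)
  if (closed && nrow(pts) >= 3) {
    P <- pts
    if (any(P[1, ] != P[nrow(P), ])) P <- rbind(P, P[1, ])
    y1 <- P[-nrow(P), 1]; x1 <- P[-nrow(P), 2]
    y2 <- P[-1, 1]; x2 <- P[-1, 2]
    for (r in seq_len(dim[1])) {
      cr <- (y1 <= r & y2 > r) | (y2 <= r & y1 > r)
      if (!any(cr)) next
      xs <- sort(x1[cr] + (r - y1[cr]) / (y2[cr] - y1[cr]) * (x2[cr] - x1[cr]))
      for (k in seq(1, length(xs) - 1, by = 2)) {
        c0 <- ceiling(xs[k]); c1 <- floor(xs[k + 1])
        if (c1 >= c0) {
          c0 <- max(1, c0); c1 <- min(dim[2], c1)
          if (c1 >= c0) mask[r, c0:c1] <- TRUE
        }
      }
    }
  }
  # boundary pixels count as interior
  for (i in seq_len(nrow(pts) - 1)) {
    seg_len <- max(abs(pts[i + 1, ] - pts[i, ]), 1)
    tt <- seq(0, 1, length.out = ceiling(seg_len) * 2 + 1)
    rr <- round(pts[i, 1] + tt * (pts[i + 1, 1] - pts[i, 1]))
    cc <- round(pts[i, 2] + tt * (pts[i + 1, 2] - pts[i, 2]))
    ok <- rr >= 1 & rr <= dim[1] & cc >= 1 & cc <= dim[2]
    mask[cbind(rr[ok], cc[ok])] <- TRUE
  }
  mask
}
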