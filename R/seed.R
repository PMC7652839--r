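# Initial-crack construction: manual polyline seeds, and the automatic
# ray-sweep procedure that casts a fan of rays from an apex outside the
# window and seeds the crack through the first edge-detector hits.

#' Ray-sweep fan angles
#'
#' For a square window of side `s` viewed from an apex at distance `N * s`
#' beyond the midpoint of one side, the fan subtends
#' `phi = 2 * atan(1 / (2 * N))`; dividing by `m` gives the angular
#' increment. Returns the `m + 1` ray angles `i * phi / m`, `i = 0..m`,
#' measured from the ray through one corner towards the other.
#'
#' @param N Apex distance as a multiple of the window side (>= 1).
#' @param m Number of angular subdivisions (integer >= 2).
#' @return List with `phi` (total fan angle, radians) and `angles`
#'   (increasing vector of length `m + 1` spanning exactly `[0, phi]`).
#' @export
sweep_angles <- function(N, m) {
  check_scalar(N, "N")
  if (N < 1) stop_param("`N` must be >= 1")
  if (!is.numeric(m) || length(m) != 1 || m != round(m) || m < 2)
    stop_param("`m` must be an integer >= 2")
  phi <- 2 * atan(1 / (2 * N))
  list(phi = phi, angles = seq(0, phi, length.out = m + 1))
}

# --- Canny edge detection on a window --------------------------------------
# Gaussian-derivative gradients, non-maximum suppression quantised to four
# directions, and two-threshold hysteresis grown by 8-neighbour dilation.

#' Canny edge map
#'
#' @param window Numeric matrix (grayscale window).
#' @param sigma Gaussian smoothing scale in pixels. Default 1.5.
#' @param low,high Hysteresis thresholds as quantiles of the nonzero
#'   gradient magnitude. Defaults 0.70 and 0.90.
#' @return Logical matrix of edge pixels.
#' @export
canny_edges <- function(window, sigma = 1.5, low = 0.70, high = 0.90) {
  check_image(window, "window")
  g <- gradient_components(window, sigma)
  mag <- sqrt(g$dr^2 + g$dc^2)
  nr <- nrow(mag); nc <- ncol(mag)
  if (max(mag) < 1e-8) return(matrix(FALSE, nr, nc))  # featureless window
  ang <- atan2(g$dr, g$dc) %% pi          # orientation modulo pi
  sector <- as.integer(floor(ang / (pi / 4) + 0.5)) %% 4L  # 0:E,1:NE,2:N,3:NW
  shift <- function(m, dr, dc) {
    out <- matrix(0, nr, nc)
    rs <- max(1, 1 + dr):min(nr, nr + dr); cs <- max(1, 1 + dc):min(nc, nc + dc)
    out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
    out
  }
  offs <- list(c(0, 1), c(1, 1), c(1, 0), c(1, -1))  # (drow, dcol) per sector
  nms <- matrix(FALSE, nr, nc)
  for (s in 0:3) {
    o <- offs[[s + 1]]
    sel <- sector == s
    nms[sel] <- mag[sel] >= shift(mag, o[1], o[2])[sel] &
                mag[sel] >= shift(mag, -o[1], -o[2])[sel]
  }
  qs <- stats::quantile(mag[mag > 0], c(low, high), names = FALSE)
  strong <- nms & mag >= qs[2]
  weak <- nms & mag >= qs[1]
  # hysteresis: grow strong into weak through 8-connectivity
  cur <- strong
  repeat {
    grown <- cur
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      grown <- grown | shift(cur, dr, dc)
    }
    grown <- grown & weak
    nxt <- cur | grown
    if (identical(nxt, cur)) break
    cur <- nxt
  }
  cur
}

# March along a ray from `from` towards direction `dir` (unit, (row, col));
# return the first TRUE pixel of `edge` hit inside the matrix, or NULL. The
# apex sits well outside the window, so the march must cover the apex
# distance plus the window diagonal.
ray_first_hit <- function(edge, from, dir, step = 0.5) {
  nr <- nrow(edge); nc <- ncol(edge)
  tmax <- sqrt((nr - from[1])^2 + (nc - from[2])^2) +
          sqrt(from[1]^2 + from[2]^2) + sqrt(nr^2 + nc^2)
  inside_seen <- FALSE
  for (t in seq(0, tmax, by = step)) {
    p <- from + t * dir
    r <- round(p[1]); c <- round(p[2])
    if (r < 1 || r > nr || c < 1 || c > nc) {
      if (inside_seen) break              # left the window: no hit ahead
      next
    }
    inside_seen <- TRUE
    if (edge[r, c]) return(c(p[1], p[2]))
  }
  NULL
}

#' Automatic initial crack by ray sweep
#'
#' Casts a fan of rays from an apex placed `N` window-sides beyond one side
#' of the window and records the first Canny edge hit on each ray; the seed
#' is a short segment of the total-least-squares line through those hits.
#' All four apex placements (above, below, left, right of the window) are
#' tried and the one collecting the most ray hits wins, so no orientation
#' hint is needed.
#'
#' @param window Numeric matrix (the first local window, grayscale).
#' @param N Apex distance multiple (>= 1). Default 2.
#' @param m Angular subdivisions (>= 2). Default 8.
#' @param sigma,low,high Passed to [canny_edges()].
#' @param seed_len Length of the returned seed segment in pixels (3-5).
#'   Default 4.
#' @return A `crack_seed`: list with `points` (pixel coordinates, window
#'   frame), `source = "automatic"`, and `hits` (the raw ray hits).
#' @export
auto_initial_crack <- function(window, N = 2, m = 8, sigma = 1.5,
                               low = 0.70, high = 0.90, seed_len = 4) {
  check_image(window, "window")
  sw <- sweep_angles(N, m)
  edge <- canny_edges(window, sigma, low, high)
  nr <- nrow(window); nc <- ncol(window)
  s <- max(nr, nc)
  half <- sw$phi / 2
  placements <- list(
    list(apex = c(-N * s, (nc + 1) / 2), axis = c(1, 0)),   # from above
    list(apex = c(nr + 1 + N * s, (nc + 1) / 2), axis = c(-1, 0)),
    list(apex = c((nr + 1) / 2, -N * s), axis = c(0, 1)),   # from the left
    list(apex = c((nr + 1) / 2, nc + 1 + N * s), axis = c(0, -1))
  )
  best <- NULL
  for (pl in placements) {
    hits <- list()
    for (a in sw$angles - half) {
      cs <- cos(a); sn <- sin(a)
      d <- pl$axis * cs + c(-pl$axis[2], pl$axis[1]) * sn
      h <- ray_first_hit(edge, pl$apex, d)
      if (!is.null(h)) hits[[length(hits) + 1]] <- h
    }
    if (is.null(best) || length(hits) > length(best$hits))
      best <- list(hits = hits, placement = pl)
  }
  hits <- best$hits
  if (length(hits) < 2)
    rlang::abort("automatic seeding found fewer than 2 edge hits; supply a manual seed",
                 class = c("crackseg_seed_not_found", "crackseg_error"))
  P <- do.call(rbind, hits)
  # a curved boundary makes the full fan of hits sag inward; fit the seed
  # only through the hits nearest the central one
  ctr0 <- P[which.min(rowSums((sweep(P, 2, colMeans(P)))^2)), ]
  keep <- sqrt((P[, 1] - ctr0[1])^2 + (P[, 2] - ctr0[2])^2) <= max(seed_len, 5)
  if (sum(keep) >= 2) P <- P[keep, , drop = FALSE]
  ctr <- colMeans(P)
  dirv <- fit_direction(P)$direction
  tt <- (P[, 1] - ctr[1]) * dirv[1] + (P[, 2] - ctr[2]) * dirv[2]
  half_len <- min(seed_len / 2, (max(tt) - min(tt)) / 2)
  if (half_len <= 0) half_len <- seed_len / 2
  pts <- rbind(ctr - half_len * dirv, ctr + half_len * dirv)
  structure(list(points = pts, source = "automatic", hits = P),
            class = "crack_seed")
}

#' Manual initial crack
#'
#' Validates a user-supplied short polyline along the target boundary.
#' Consecutive duplicate points are dropped with a warning.
#'
#' @param points Matrix (or two-column data frame) of at least two `(row,
#'   col)` pixel coordinates, ordered along the boundary.
#' @return A `crack_seed` with `source = "manual"`.
#' @export
manual_initial_crack <- function(points) {
  points <- as.matrix(points)
  if (ncol(points) != 2 || nrow(points) < 2)
    stop_input("a manual seed needs at least 2 (row, col) points")
  dup <- c(FALSE, rowSums(abs(diff(points))) == 0)
  if (any(dup)) {
    rlang::warn("dropping consecutive duplicate seed points")
    points <- points[!dup, , drop = FALSE]
  }
  if (nrow(points) < 2)
    stop_input("a manual seed needs at least 2 distinct points")
  structure(list(points = points, source = "manual", hits = NULL),
            class = "crack_seed")
}

#' @export
print.crack_seed <- function(x, ...) {
  cat(sprintf("<crack_seed> %s, %d points from (%.1f, %.1f) to (%.1f, %.1f)\n",
              x$source, nrow(x$points),
              x$points[1, 1], x$points[1, 2],
              x$points[nrow(x$points), 1], x$points[nrow(x$points), 2]))
  invisible(x)
}

# Snap an ordered polyline of (row, col) points to a 4-connected node path
# (dominant-axis staircase between consecutive rounded points).
snap_path <- function(pts) {
  pts <- round(rbind(pts))
  out <- pts[1, , drop = FALSE]
  for (k in seq_len(nrow(pts))[-1]) {
    cur <- out[nrow(out), ]; tgt <- pts[k, ]
    while (any(cur != tgt)) {
      d <- tgt - cur
      step <- if (abs(d[2]) >= abs(d[1])) c(0, sign(d[2])) else c(sign(d[1]), 0)
      cur <- cur + step
      out <- rbind(out, cur)
    }
  }
  out[!duplicated(out), , drop = FALSE]
}
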