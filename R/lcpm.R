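# The local crack-propagation driver: iterate small overlapping windows along
# the boundary, run the fracture simulation in each, and integrate the
# per-window cracks into one contour.

#' LCPM configuration
#'
#' All tunable parameters of the windowed crack-propagation pipeline, with
#' validated defaults.
#'
#' @param L Window half-size in pixels; each local model covers
#'   `(2L+1) x (2L+1)` pixels. Default 15.
#' @param alpha Distance between consecutive window centres (pixels). Must
#'   satisfy `0 < alpha < 2L` so adjacent windows overlap and the previous
#'   crack end can seed the next model. Default `L`.
#' @param H Maximum plate thickness (see [thickness_map()]). Default 10.
#' @param sigma Gaussian gradient scale in pixels. Default 1.5.
#' @param gamma Power-law contrast exponent. Default 2.
#' @param transform_scope `"window"` (default) rescales and gamma-transforms
#'   the gradient within each local window, so local contrast is amplified
#'   without interference from remote regions; `"global"` transforms once.
#' @param material A [material_params()].
#' @param load A [load_spec()].
#' @param gap_max Largest groove interruption (px) a single front may be
#'   forced across. Default 3.
#' @param merge_tol Tip-to-tip distance (px) within which opposing fronts or
#'   contour ends are joined by a straight bridge. Default 3.
#' @param closure_eps Closure tolerance: the contour closes when the tip
#'   comes within this distance (px) of the starting seed after at least 3
#'   windows. Default `alpha`.
#' @param max_windows Iteration cap. Default 500.
#' @param seed_len Length (edges) of the crack tail re-used as the next
#'   window's seed. Default 4.
#' @param sweep_N,sweep_m Ray-sweep parameters for automatic seeding.
#'   Defaults 2 and 8.
#' @param canny_low,canny_high Edge-detector hysteresis quantiles. Defaults
#'   0.70, 0.90.
#' @param probe_max Farthest distance (px) ahead of a stalled tip searched
#'   for the boundary resuming beyond a gap. Default `2 * L`.
#' @param probe_frac Fraction of the crack's median gradient that counts as
#'   the boundary resuming. Default 0.3.
#' @param max_respawns How many second fronts may be spawned across wide
#'   gaps before the contour is returned open. Default 3.
#' @return An `lcpm_config` list.
#' @export
lcpm_config <- function(L = 15, alpha = L, H = 10, sigma = 1.5, gamma = 2,
                        transform_scope = c("window", "global"),
                        material = material_params(), load = load_spec(),
                        gap_max = 3, merge_tol = 3, closure_eps = alpha,
                        max_windows = 500, seed_len = 4,
                        sweep_N = 2, sweep_m = 8,
                        canny_low = 0.70, canny_high = 0.90,
                        probe_max = 2 * L, probe_frac = 0.3,
                        max_respawns = 3) {
  transform_scope <- match.arg(transform_scope)
  check_scalar(L, "L"); check_scalar(H, "H")
  check_scalar(sigma, "sigma"); check_scalar(gamma, "gamma")
  if (L < 4) stop_param("`L` must be >= 4")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 2 * L)
    stop_param(sprintf("`alpha` must satisfy 0 < alpha < 2L (got alpha = %s, L = %s)",
                       format(alpha), format(L)))
  stopifnot(inherits(material, "material_params"), inherits(load, "load_spec"))
  structure(list(L = as.integer(L), alpha = alpha, H = H, sigma = sigma,
                 gamma = gamma, transform_scope = transform_scope,
                 material = material, load = load,
                 gap_max = as.integer(gap_max), merge_tol = merge_tol,
                 closure_eps = closure_eps, max_windows = as.integer(max_windows),
                 seed_len = as.integer(seed_len),
                 sweep_N = sweep_N, sweep_m = as.integer(sweep_m),
                 canny_low = canny_low, canny_high = canny_high,
                 probe_max = probe_max, probe_frac = probe_frac,
                 max_respawns = as.integer(max_respawns)),
            class = "lcpm_config")
}

#' Map a window-local crack to global image coordinates
#'
#' Translates crack vertices from window-local mesh coordinates to global
#' pixel coordinates, ordered from entry to tip.
#'
#' @param crack A `crack_path` (or bare vertex matrix) in window-local node
#'   coordinates.
#' @param window A window extracted with [extract_window()] (carrying the
#'   `rows`/`cols` attributes), or a [window_spec()] (assumed unclamped).
#' @param index Window index stored with the boundary. Default 1.
#' @return A `local_boundary` tibble with columns `row`, `col`, `window`.
#' @export
crack_to_boundary <- function(crack, window, index = 1L) {
  verts <- if (inherits(crack, "crack_path")) crack$vertices else rbind(crack)
  if (is.null(verts) || nrow(verts) == 0) stop_input("empty crack")
  if (inherits(window, "window_spec")) {
    off <- window$center - window$half_size
  } else {
    off <- c(attr(window, "rows")[1], attr(window, "cols")[1])
  }
  tibble::tibble(row = verts[, 1] + off[1],
                 col = verts[, 2] + off[2],
                 window = as.integer(index))
}

# Total-least-squares line direction through a 2-D point cloud.
fit_direction <- function(P) {
  P <- rbind(P)
  ctr <- colMeans(P)
  X <- sweep(P, 2, ctr)
  C <- crossprod(X) / nrow(P)
  ev <- eigen(C, symmetric = TRUE)
  v <- ev$vectors[, 1]           # (row, col) components
  list(center = ctr, direction = v / sqrt(sum(v^2)))
}

#' Fit the local boundary direction
#'
#' Orientation of the best-fit line through the boundary points by
#' orthogonal (total-least-squares) regression, which remains well defined
#' for vertical boundaries where the ordinary slope diverges. The angle is
#' measured with the column axis as abscissa and the row axis as ordinate,
#' and normalised to `(-pi/2, pi/2]`; it equals `atan(slope)` whenever the
#' ordinary slope exists.
#'
#' @param boundary A `local_boundary` tibble (or any object with `row`/`col`
#'   columns, or a two-column matrix of `(row, col)` points).
#' @return List with `theta` (radians), `direction` (unit `(row, col)`
#'   vector) and `center` (centroid).
#' @export
fit_boundary_direction <- function(boundary) {
  P <- if (is.matrix(boundary)) boundary else cbind(boundary$row, boundary$col)
  if (nrow(unique(rbind(P))) < 2) stop_input("need at least 2 distinct points to fit a direction")
  f <- fit_direction(P)
  v <- f$direction                       # (drow, dcol)
  th <- atan2(v[1], v[2])                # x = col, y = row
  if (th <= -pi / 2) th <- th + pi
  if (th > pi / 2) th <- th - pi
  if (th == -pi / 2) th <- pi / 2
  list(theta = th, direction = v, center = f$center)
}

#' Next window centre along the boundary
#'
#' Moves the window centre a distance `alpha` along the fitted boundary
#' direction: `C' = C +/- alpha * (sin(theta), cos(theta))` in `(row, col)`.
#' The sign is chosen so the step continues the direction of travel
#' (positive projection on `prev_step`).
#'
#' @param center Current centre `(row, col)`.
#' @param theta Boundary angle from [fit_boundary_direction()].
#' @param alpha Step length in pixels (> 0).
#' @param prev_step Direction of the previous step (any nonzero vector).
#' @return New centre; the Euclidean step length is exactly `alpha`.
#' @export
next_center <- function(center, theta, alpha, prev_step) {
  if (!is.numeric(alpha) || alpha <= 0) stop_param("`alpha` must be > 0")
  step <- alpha * c(sin(theta), cos(theta))
  if (sum(step * prev_step) < 0) step <- -step
  center + step
}

# --- driver internals ------------------------------------------------------

clamp_center <- function(center, dim) {
  pmin(pmax(round(center), 1), dim)
}

# Search ahead of a stalled tip for the gradient rising again (the boundary
# resuming on the far side of a gap). A narrow fan perpendicular to the ray
# absorbs boundary curvature across the gap.
probe_resume <- function(IG, tip, dir, ref, probe_max, probe_frac) {
  dim <- dim(IG)
  perp <- c(-dir[2], dir[1])
  for (t in seq(3, probe_max, by = 1)) {
    lat_max <- min(3, ceiling(t / 4))
    for (lat in c(0, seq_len(lat_max))) for (s in if (lat == 0) 1 else c(-1, 1)) {
      p <- round(tip + t * dir + s * lat * perp)
      if (any(p < 2) || p[1] > dim[1] - 1 || p[2] > dim[2] - 1) next
      patch <- IG[(p[1] - 1):(p[1] + 1), (p[2] - 1):(p[2] + 1)]
      if (max(patch) >= probe_frac * ref) return(list(point = p, dist = t))
    }
  }
  NULL
}

# Assemble one window's plate model and run the fracture simulation.
run_window <- function(IG_src, image_raw, center, seed_global, config, ramp_cap,
                       momentum_hint = NULL) {
  spec <- window_spec(center, config$L)
  W <- extract_window(IG_src, spec)
  off <- c(attr(W, "rows")[1], attr(W, "cols")[1])
  M <- if (config$transform_scope == "window") enhance_gradient(W, config$gamma) else W
  th <- thickness_map(M, config$H)
  if (is_degenerate(th)) {
    return(list(degenerate = TRUE, spec = spec, off = off))
  }
  mesh <- build_mesh(th, 1, config$material)
  seed_local <- sweep(seed_global, 2, off)
  keep <- seed_local[, 1] > 0 & seed_local[, 1] < mesh$nr &
          seed_local[, 2] > 0 & seed_local[, 2] < mesh$nc
  seed_local <- seed_local[keep, , drop = FALSE]
  if (nrow(seed_local) < 2) return(list(no_seed = TRUE, spec = spec, off = off))
  # re-snap: clamped windows can break 4-connectivity of the tail
  seed_local <- snap_path(seed_local)
  load_cfg <- config$load
  load_cfg$ramp_cap <- ramp_cap
  cp <- propagate_crack(mesh, seed_local, config$material, load_cfg,
                        gap_max = config$gap_max,
                        max_len = 4L * config$L,
                        momentum_hint = momentum_hint)
  list(crack = cp, spec = spec, off = off, degenerate = FALSE, no_seed = FALSE)
}

#' Resume a stalled front across a boundary gap
#'
#' Implements the wide-gap strategy: when a front has stalled (the groove is
#' interrupted by more than `gap_max` groove-free pixels), search along the
#' stalled direction for the image gradient rising again, and start a second
#' front there (seeded automatically from the local edge map, falling back
#' to a short directional seed), oriented to continue the same circulation.
#' The junction between the stalled tip and the new seed is recorded as a
#' straight bridge for contour integration.
#'
#' @param state Driver state list as maintained by [run_lcpm()]: needs
#'   `IG` (global gradient), `image` (raw grayscale), `tip`, `tip_dir`,
#'   `crack_points` (matrix of contour points so far) and `config`.
#' @return The state with fields `seed` (new global seed points), `center`
#'   (new window centre), `bridge` (two-row matrix tip -> new start) set,
#'   or `state$failed = TRUE` when no resumption was found.
#' @export
handle_stall <- function(state) {
  cfg <- state$config
  # reference gradient level: median along the crack so far
  idx <- cbind(pmin(pmax(round(state$crack_points[, 1]), 1), dim(state$IG)[1]),
               pmin(pmax(round(state$crack_points[, 2]), 1), dim(state$IG)[2]))
  ref <- stats::median(state$IG[idx])
  hit <- probe_resume(state$IG, state$tip, state$tip_dir, ref,
                      cfg$probe_max, cfg$probe_frac)
  if (is.null(hit)) { state$failed <- TRUE; return(state) }
  # snap the new seed onto the resumed boundary: strongest gradient pixel
  # near the hit, oriented along the local edge ridge
  dimg <- dim(state$IG)
  rr <- max(2, hit$point[1] - 2):min(dimg[1] - 1, hit$point[1] + 2)
  cc <- max(2, hit$point[2] - 2):min(dimg[2] - 1, hit$point[2] + 2)
  sub <- state$IG[rr, cc, drop = FALSE]
  ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
  pstar <- c(rr[ij[1]], cc[ij[2]])
  nb <- 5
  rr2 <- max(1, pstar[1] - nb):min(dimg[1], pstar[1] + nb)
  cc2 <- max(1, pstar[2] - nb):min(dimg[2], pstar[2] + nb)
  ridge <- which(state$IG[rr2, cc2, drop = FALSE] >=
                   0.5 * state$IG[pstar[1], pstar[2]], arr.ind = TRUE)
  edge_dir <- if (nrow(ridge) >= 2) {
    fit_direction(cbind(rr2[ridge[, 1]], cc2[ridge[, 2]]))$direction
  } else state$tip_dir
  seed2 <- rbind(pstar - cfg$seed_len / 2 * edge_dir,
                 pstar + cfg$seed_len / 2 * edge_dir)
  # orient the new seed to continue the same circulation
  d2 <- seed2[nrow(seed2), ] - seed2[1, ]
  if (sum(d2 * state$tip_dir) < 0) seed2 <- seed2[rev(seq_len(nrow(seed2))), ]
  state$seed <- snap_path(seed2)
  state$center <- clamp_center(colMeans(seed2), dim(state$IG))
  state$bridge <- rbind(state$tip, state$seed[1, ])
  state$failed <- FALSE
  state
}

#' Integrate per-window boundary fragments into one contour
#'
#' Concatenates the fragments in window order, removes near-duplicate points
#' from overlapping runs (closer than 1.5 px to a recently kept point),
#' interpolates recorded bridges (gap junctions, closure) at unit spacing,
#' applies moving-average smoothing (window 5; circular for closed contours,
#' endpoints preserved for open ones), and orients closed contours
#' counter-clockwise (with the column axis right and the row axis up).
#'
#' @param fragments A `local_boundary` tibble (or list of them) with
#'   `row`, `col`, `window` columns, ordered along the boundary.
#' @param bridges Optional list of two-row matrices (from, to) to insert as
#'   straight segments where consecutive fragments do not touch.
#' @param closed Should the contour be closed? Default FALSE.
#' @param smooth_window Moving-average half-support (full width). Default 5.
#' @return A `contour` tibble with columns `row`, `col`, `window` (NA for
#'   bridge points) and attributes `closed`.
#' @export
merge_and_smooth <- function(fragments, bridges = list(), closed = FALSE,
                             smooth_window = 5) {
  if (is.list(fragments) && !is.data.frame(fragments))
    fragments <- do.call(rbind, fragments)
  pts <- cbind(fragments$row, fragments$col)
  win <- fragments$window
  if (nrow(pts) < 2) stop_input("nothing to merge")

  # insert bridges where they belong (matched by their endpoints)
  insert_bridge <- function(pts, win, br) {
    d_from <- (pts[, 1] - br[1, 1])^2 + (pts[, 2] - br[1, 2])^2
    at <- which.min(d_from)
    seg_len <- max(abs(br[2, ] - br[1, ]))
    if (seg_len >= 1) {
      tt <- seq(0, 1, length.out = max(2, ceiling(seg_len) + 1))
      seg <- cbind(br[1, 1] + tt * (br[2, 1] - br[1, 1]),
                   br[1, 2] + tt * (br[2, 2] - br[1, 2]))
      seg <- seg[-c(1, nrow(seg)), , drop = FALSE]
      if (nrow(seg)) {
        pts <- rbind(pts[seq_len(at), , drop = FALSE], seg,
                     pts[-seq_len(at), , drop = FALSE])
        win <- c(win[seq_len(at)], rep(NA_integer_, nrow(seg)), win[-seq_len(at)])
      }
    }
    list(pts = pts, win = win)
  }
  for (br in bridges) {
    tmp <- insert_bridge(pts, win, br)
    pts <- tmp$pts; win <- tmp$win
  }

  # drop near-duplicates from overlapping runs
  keep <- rep(TRUE, nrow(pts))
  last_kept <- 1
  for (i in 2:nrow(pts)) {
    look <- which(keep[max(1, i - 10):(i - 1)]) + max(1, i - 10) - 1
    d <- sqrt((pts[look, 1] - pts[i, 1])^2 + (pts[look, 2] - pts[i, 2])^2)
    if (any(d < 0.5)) keep[i] <- FALSE
  }
  pts <- pts[keep, , drop = FALSE]; win <- win[keep]

  # close the loop with a straight bridge when the ends nearly meet
  if (closed) {
    gap <- pts[1, ] - pts[nrow(pts), ]
    glen <- sqrt(sum(gap^2))
    if (glen > 1) {
      nseg <- ceiling(glen)
      tt <- seq(0, 1, length.out = nseg + 1)[-c(1, nseg + 1)]
      seg <- cbind(pts[nrow(pts), 1] + tt * gap[1], pts[nrow(pts), 2] + tt * gap[2])
      pts <- rbind(pts, seg)
      win <- c(win, rep(NA_integer_, nrow(seg)))
    }
  }

  # moving-average smoothing
  n <- nrow(pts)
  if (n >= smooth_window && smooth_window > 1) {
    half <- smooth_window %/% 2
    sm <- pts
    for (i in seq_len(n)) {
      if (closed) {
        id <- ((i - half - 1):(i + half - 1)) %% n + 1
      } else {
        if (i <= half || i > n - half) next   # endpoints preserved exactly
        id <- (i - half):(i + half)
      }
      sm[i, ] <- colMeans(pts[id, , drop = FALSE])
    }
    pts <- sm
  }

  # counter-clockwise orientation for closed contours (x = col, y = -row)
  if (closed && n >= 3) {
    x <- pts[, 2]; y <- -pts[, 1]
    area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
    if (area < 0) { pts <- pts[rev(seq_len(n)), , drop = FALSE]; win <- rev(win) }
  }

  out <- tibble::tibble(row = pts[, 1], col = pts[, 2], window = win)
  attr(out, "closed") <- closed
  class(out) <- c("contour", class(out))
  out
}

#' Segment an image with the local crack-propagation method
#'
#' Runs the full pipeline: global Gaussian-gradient transform, then
#' iterated local windows in which the enhanced gradient is turned into a
#' variable-thickness plate and a crack is propagated along the groove
#' carved by the target boundary. Each window's crack seeds the next; the
#' window centre advances a distance `alpha` along the fitted boundary
#' direction. Boundary gaps are crossed by stress concentration (short
#' gaps) or by spawning a second front beyond the gap (wide gaps). The
#' contour closes when the crack returns to its starting seed.
#'
#' @param image Numeric matrix in \[0, 1\] (or a [gray_image()]).
#' @param config An [lcpm_config()].
#' @param center `(row, col)` centre of the first window (user supplied,
#'   on or near the target boundary).
#' @param seed A `crack_seed` from [manual_initial_crack()] /
#'   [auto_initial_crack()] (window coordinates are interpreted as global
#'   when the seed is manual), or a bare matrix of global `(row, col)`
#'   points along the boundary.
#' @param auto_seed If `TRUE` and `seed` is `NULL`, seed automatically in
#'   the first window by ray sweep.
#' @param verbose Print one line per window.
#' @return An `lcpm_result`: list with `contour` (tibble `row`, `col`,
#'   `window`), `closed` flag, `mask` (logical matrix, contour interior),
#'   `windows` (per-window log tibble), `stalls` (number of stall events),
#'   `fronts` (number of fronts used), `config`, and `dim`.
#' @export
run_lcpm <- function(image, config = lcpm_config(), center, seed = NULL,
                     auto_seed = is.null(seed), verbose = FALSE) {
  if (inherits(image, "gray_image")) spacing <- attr(image, "pixel_spacing") else spacing <- 1
  img <- unclass(image); attributes(img) <- attributes(img)["dim"]
  check_image(img)
  stopifnot(inherits(config, "lcpm_config"))
  dimg <- dim(img)
  center <- clamp_center(center, dimg)

  IG <- gaussian_gradient(img, config$sigma)
  IG_src <- if (config$transform_scope == "global") enhance_gradient(IG, config$gamma) else IG

  if (is.null(seed) && auto_seed) {
    spec0 <- window_spec(center, config$L)
    W0 <- extract_window(img, spec0)
    off0 <- c(attr(W0, "rows")[1], attr(W0, "cols")[1])
    s0 <- auto_initial_crack(W0, N = config$sweep_N, m = config$sweep_m,
                             sigma = config$sigma, low = config$canny_low,
                             high = config$canny_high, seed_len = config$seed_len)
    seed_pts <- sweep(s0$points, 2, -off0)
  } else if (inherits(seed, "crack_seed")) {
    seed_pts <- seed$points
  } else if (!is.null(seed)) {
    seed_pts <- as.matrix(seed)
  } else {
    stop_input("supply `seed` or set `auto_seed = TRUE`")
  }
  seed_snapped <- snap_path(seed_pts)
  if (nrow(seed_snapped) < 2) stop_input("seed collapses to fewer than 2 mesh nodes")

  start_point <- seed_snapped[1, ]
  crack_points <- seed_snapped
  fragments <- list(tibble::tibble(row = seed_snapped[, 1], col = seed_snapped[, 2],
                                   window = 0L))
  bridges <- list()
  winlog <- list()
  ramp_cap <- NULL
  prev_step <- unitv(seed_snapped[nrow(seed_snapped), ] - seed_snapped[1, ])
  seed_global <- seed_snapped
  stalls <- 0L
  fronts <- 1L
  closed <- FALSE
  done <- FALSE
  iter <- 0L

  while (!done && iter < config$max_windows) {
    iter <- iter + 1L
    np <- nrow(crack_points)
    hint <- if (np >= 11) unitv(crack_points[np, ] - crack_points[np - 10, ]) else prev_step
    rw <- run_window(IG_src, img, center, seed_global, config, ramp_cap,
                     momentum_hint = unitv(hint))

    stalled_now <- FALSE
    if (isTRUE(rw$degenerate) || isTRUE(rw$no_seed)) {
      stalled_now <- TRUE
      tip <- crack_points[nrow(crack_points), ]
      tip_dir <- prev_step
    } else {
      cp <- rw$crack
      if (is.null(ramp_cap)) ramp_cap <- cp$ramp_cap
      glob <- sweep(cp$vertices, 2, -rw$off)
      # seed vertices the new window retracted were dead ends (e.g. a corner
      # overshoot cut off by the previous window border); prune them from the
      # contour so no spur survives integration
      in_glob <- apply(seed_global, 1, function(p)
        any(glob[, 1] == p[1] & glob[, 2] == p[2]))
      if (any(!in_glob)) {
        drop_pts <- seed_global[!in_glob, , drop = FALSE]
        for (q in seq_len(nrow(drop_pts))) {
          hit <- which(crack_points[, 1] == drop_pts[q, 1] &
                       crack_points[, 2] == drop_pts[q, 2])
          if (length(hit)) crack_points <- crack_points[-max(hit), , drop = FALSE]
          for (fi in rev(seq_along(fragments))) {
            fh <- which(fragments[[fi]]$row == drop_pts[q, 1] &
                        fragments[[fi]]$col == drop_pts[q, 2])
            if (length(fh)) {
              fragments[[fi]] <- fragments[[fi]][-max(fh), ]
              break
            }
          }
        }
      }
      # the re-cracked seed tail duplicates existing contour points; keep new ones
      is_dup <- duplicated(rbind(crack_points, glob))[-seq_len(nrow(crack_points))]
      newpts <- glob[!is_dup, , drop = FALSE]
      if (nrow(newpts)) {
        crack_points <- rbind(crack_points, newpts)
        fragments[[length(fragments) + 1L]] <-
          tibble::tibble(row = newpts[, 1], col = newpts[, 2], window = iter)
      }
      tip <- crack_points[nrow(crack_points), ]
      nb <- nrow(crack_points)
      tip_dir <- if (nb >= 2)
        unitv(tip - crack_points[max(1, nb - 5), ]) else prev_step
      stalled_now <- cp$stalled
      fitw <- tryCatch(fit_boundary_direction(glob), error = function(e) NULL)
      winlog[[iter]] <- tibble::tibble(
        window = iter, center_row = center[1], center_col = center[2],
        theta = if (is.null(fitw)) NA_real_ else fitw$theta,
        n_new = nrow(newpts), stalled = stalled_now,
        onset_max = if (nrow(cp$onsets)) max(cp$onsets$onset) else NA_real_)
    }

    if (verbose)
      message(sprintf("win %d: centre (%d,%d) tip (%g,%g) stalled=%s pts=%d",
                      iter, center[1], center[2], tip[1], tip[2],
                      stalled_now, nrow(crack_points)))

    # closure test
    if (iter >= 3 && sqrt(sum((tip - start_point)^2)) <= config$closure_eps &&
        nrow(crack_points) > 3 * config$seed_len) {
      closed <- TRUE
      done <- TRUE
      break
    }
    # image border exit
    if (tip[1] <= 1 || tip[1] >= dimg[1] - 1 || tip[2] <= 1 || tip[2] >= dimg[2] - 1) {
      done <- TRUE
      break
    }

    if (stalled_now) {
      stalls <- stalls + 1L
      if (fronts > config$max_respawns) { done <- TRUE; break }
      st <- handle_stall(list(IG = IG, image = img, tip = tip,
                              tip_dir = if (all(tip_dir == 0)) prev_step else tip_dir,
                              crack_points = crack_points, config = config))
      if (isTRUE(st$failed)) { done <- TRUE; break }
      fronts <- fronts + 1L
      bridges[[length(bridges) + 1L]] <- st$bridge
      seed_global <- st$seed
      crack_points <- rbind(crack_points, seed_global)
      fragments[[length(fragments) + 1L]] <-
        tibble::tibble(row = seed_global[, 1], col = seed_global[, 2], window = iter)
      center <- st$center
      prev_step <- unitv(seed_global[nrow(seed_global), ] - seed_global[1, ])
      next
    }

    # next window: centre moves alpha along the fitted direction; seed is the
    # crack tail inside the new window
    glob_this <- sweep(rw$crack$vertices, 2, -rw$off)
    fit <- tryCatch(fit_boundary_direction(glob_this), error = function(e) NULL)
    if (is.null(fit)) { done <- TRUE; break }
    new_center <- next_center(center, fit$theta, config$alpha, prev_step)
    prev_step <- new_center - center
    center <- clamp_center(new_center, dimg)

    tail_n <- min(max(config$seed_len, 10L) + 1L, nrow(crack_points))
    tail_pts <- crack_points[(nrow(crack_points) - tail_n + 1L):nrow(crack_points), , drop = FALSE]
    inside <- tail_pts[, 1] > center[1] - config$L & tail_pts[, 1] < center[1] + config$L &
              tail_pts[, 2] > center[2] - config$L & tail_pts[, 2] < center[2] + config$L
    if (sum(inside) < 2) {
      center <- clamp_center(tip - round(config$L / 2 * tip_dir), dimg)
      inside <- tail_pts[, 1] > center[1] - config$L & tail_pts[, 1] < center[1] + config$L &
                tail_pts[, 2] > center[2] - config$L & tail_pts[, 2] < center[2] + config$L
      if (sum(inside) < 2) { done <- TRUE; break }
    }
    seed_global <- tail_pts[inside, , drop = FALSE]
  }

  contour <- merge_and_smooth(do.call(rbind, fragments), bridges = bridges,
                              closed = closed)
  mask <- contour_mask(contour, dimg)
  structure(list(contour = contour, closed = closed, mask = mask,
                 windows = if (length(winlog)) do.call(rbind, winlog) else
                   tibble::tibble(window = integer(), center_row = numeric(),
                                  center_col = numeric(), theta = numeric(),
                                  n_new = integer(), stalled = logical(),
                                  onset_max = numeric()),
                 stalls = stalls, fronts = fronts,
                 raw_points = crack_points,
                 config = config, dim = dimg, pixel_spacing = spacing,
                 ramp_cap = ramp_cap),
            class = "lcpm_result")
}

#' @export
print.lcpm_result <- function(x, ...) {
  cat(sprintf("<lcpm_result> %s contour, %d points, %d windows, %d front(s), %d stall(s)\n",
              if (x$closed) "closed" else "open", nrow(x$contour),
              nrow(x$windows), x$fronts, x$stalls))
  invisible(x)
}
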