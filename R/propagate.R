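# Quasi-static brittle crack growth.
#
# The load is a pair of equal-and-opposite nodal force patches straddling the
# crack just behind the tip (Mode-I opening), kept normal to the crack at the
# tip and ramped linearly from zero. The solution is linear in the load, so
# each crack configuration needs a single unit-load solve: the onset force is
# max_principal_stress / sigma1(unit load) at the critical near-tip element,
# and the ramp loop reduces to finding the first ramp increment at or above
# that force. If the cap is reached without extension the front has hit a
# boundary gap: the tip may be pushed straight across a short gap (stress
# concentration carries the crack over groove-free pixels), after which
# normal growth resumes; longer gaps stall the front.

#' Load specification for crack driving
#'
#' @param patch_radius Radius (px) of the two force patches around the point
#'   just behind the tip. Default 3.
#' @param patch_offset How far behind the tip the patch pair is centred (px).
#'   Default 2.
#' @param ramp_cap Maximum total force. `NULL` (default) auto-calibrates on
#'   the initial configuration: the cap is `ramp_safety` times the onset
#'   force of the seed crack — large enough to break the groove anywhere
#'   along the window, far below what full-thickness plate needs, so the
#'   crack cannot run off through ungrooved material.
#' @param ramp_steps Number of linear ramp increments up to the cap.
#'   Default 50.
#' @param ramp_safety Cap calibration factor. Default 3.
#' @return A `load_spec` list.
#' @export
load_spec <- function(patch_radius = 3, patch_offset = 2,
                      ramp_cap = NULL, ramp_steps = 50L, ramp_safety = 3) {
  check_scalar(patch_radius, "patch_radius")
  check_scalar(patch_offset, "patch_offset")
  check_scalar(ramp_steps, "ramp_steps")
  check_scalar(ramp_safety, "ramp_safety")
  if (!is.null(ramp_cap)) check_scalar(ramp_cap, "ramp_cap")
  structure(list(patch_radius = patch_radius, patch_offset = patch_offset,
                 ramp_cap = ramp_cap, ramp_steps = as.integer(ramp_steps),
                 ramp_safety = ramp_safety),
            class = "load_spec")
}

# Nodal force vector (unit total force) for the twin patches behind the tip.
# `normal` is the current loading direction (unit, (row, col)).
patch_forces <- function(mesh, tip, tip_dir, normal, patch_radius, patch_offset) {
  ctr <- tip - patch_offset * tip_dir
  nodes <- mesh$nodes
  d <- sqrt((nodes[, 1] - ctr[1])^2 + (nodes[, 2] - ctr[2])^2)
  cand <- which(d <= patch_radius & !mesh$constrained)
  side <- (nodes[cand, 1] - ctr[1]) * normal[1] + (nodes[cand, 2] - ctr[2]) * normal[2]
  # split copies: side from the copy's open-face normal, not its position
  if (!is.null(mesh$split_info)) {
    si <- mesh$split_info
    for (r in seq_len(nrow(si))) {
      io <- match(si$orig[r], cand)
      if (!is.na(io)) side[io] <- si$normal_row_orig[r] * normal[1] + si$normal_col_orig[r] * normal[2]
      id <- match(si$dup[r], cand)
      if (!is.na(id)) side[id] <- si$normal_row_dup[r] * normal[1] + si$normal_col_dup[r] * normal[2]
    }
  }
  pos <- cand[side > 1e-9]
  neg <- cand[side < -1e-9]
  if (!length(pos) || !length(neg)) return(NULL)
  f <- numeric(2L * nrow(nodes))
  add <- function(f, ids, vec) {
    f[2L * ids - 1L] <- f[2L * ids - 1L] + vec[2]  # dof 1 = x = col
    f[2L * ids] <- f[2L * ids] + vec[1]            # dof 2 = y = row
    f
  }
  f <- add(f, pos, normal / length(pos))
  f <- add(f, neg, -normal / length(neg))
  f
}

# forward grid directions within +/- 90 degrees of `dir` (inclusive)
forward_dirs <- function(dir) {
  dirs <- rbind(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))
  dots <- dirs %*% dir
  dirs[dots > -1e-9, , drop = FALSE]
}

# Elements adjacent to the mesh edge between 4-neighbour nodes a and b
# (element indices, row index fastest); out-of-range elements dropped.
edge_elements <- function(mesh, a, b) {
  if (a[1] == b[1]) {                  # edge along the column direction
    ei <- c(a[1], a[1] + 1L); ej <- rep(max(a[2], b[2]), 2L)
  } else {                             # edge along the row direction
    ei <- rep(max(a[1], b[1]), 2L); ej <- c(a[2], a[2] + 1L)
  }
  keep <- ei >= 1 & ei <= mesh$nr & ej >= 1 & ej <= mesh$nc
  (ej[keep] - 1L) * mesh$nr + ei[keep]
}

# Elements with node (r, c) as a corner.
node_elements <- function(mesh, r, c) {
  ei <- c(r, r, r + 1L, r + 1L); ej <- c(c, c + 1L, c, c + 1L)
  keep <- ei >= 1 & ei <= mesh$nr & ej >= 1 & ej <= mesh$nc
  (ej[keep] - 1L) * mesh$nr + ei[keep]
}


on_border <- function(mesh, v) {
  v[1] <= 0 || v[1] >= mesh$nr || v[2] <= 0 || v[2] >= mesh$nc
}

#' Propagate a crack through a variable-thickness plate window
#'
#' Grows the seed crack quasi-statically. At each configuration the crack
#' faces are split open, the tip-local patch load is applied at unit
#' magnitude, and each of the three forward mesh edges is scored by the
#' maximum principal stress over the near-tip elements it would expose (the
#' elements beside the edge and around its far node). Only groove-adjacent
#' edges (at least one thin element beside them) are extension candidates:
#' groove-free plate can be crossed only by the gap mechanism. Elements
#' behind the tip's direction of travel are not consulted (their stress is
#' bending of the strips beside the open faces, not tip concentration), and
#' moves turning more than about 120 degrees against the recent travel
#' direction are ruled out, since within one local window the boundary is
#' close to straight. If the best score reaches the material threshold
#' within the linear load ramp, the crack extends one edge: the
#' highest-scoring edge wins; exact stress ties (a shared critical element)
#' fall back to the groove wall (a thin|thick edge) over the groove middle,
#' then to the direction perpendicular to the principal stress direction,
#' then to the previous direction. Growth stops at the window border, at the
#' path-length cap, or when the ramp cap is reached without extension (a
#' stall; short stalls may first be bridged straight across up to `gap_max`
#' pixels, and dead ends are undone by retraction).
#'
#' @param mesh A [build_mesh()] plate mesh.
#' @param seed Integer matrix (>= 2 x 2) of node coordinates of the initial
#'   crack (consecutive 4-neighbours), or a `crack_seed`.
#' @param material A [material_params()]; defaults to the mesh's material.
#' @param load_cfg A [load_spec()].
#' @param gap_max Maximum number of consecutive groove-free pixels the tip
#'   may be forced straight across. 0 disables gap crossing. Default 3.
#' @param max_len Path length cap in edges; default `4 * max(nr, nc)`.
#' @param max_backtracks On a dead-end stall the last free extension is
#'   retracted and that move banned, letting the stress field re-route the
#'   tip (a greedy pixel path can cut into the middle of a two-pixel-wide
#'   groove band and trap itself; the retraction undoes exactly that).
#'   Default 8 retractions per call.
#' @param momentum_hint Optional unit vector: the direction of travel
#'   accumulated before this call (e.g. over previous windows). Backs up the
#'   turn limits while the crack is still too short to carry that memory
#'   itself.
#' @param verbose Print one line per growth decision.
#' @return A `crack_path`: list with `vertices` (k x 2 node coordinates),
#'   `tip`, `tip_direction`, `stalled`, `onsets` (tibble of per-extension
#'   onset forces; `forced = TRUE` rows are gap crossings), `ramp_cap`,
#'   `ramp_step`.
#' @export
propagate_crack <- function(mesh, seed, material = NULL, load_cfg = load_spec(),
                            gap_max = 3L, max_len = NULL, max_backtracks = 8L,
                            momentum_hint = NULL, verbose = FALSE) {
  stopifnot(inherits(mesh, "plate_mesh"))
  if (inherits(seed, "crack_seed")) seed <- seed$points
  seed <- rbind(seed)
  if (nrow(seed) < 2) stop_input("seed must have at least 2 vertices")
  if (is.null(material)) material <- mesh$material
  if (is.null(max_len)) max_len <- 4L * max(mesh$nr, mesh$nc)
  if (any(seed[, 1] < 0 | seed[, 1] > mesh$nr | seed[, 2] < 0 | seed[, 2] > mesh$nc))
    stop_input("seed lies outside the mesh")

  crack <- seed
  tip_dir <- unitv(crack[nrow(crack), ] - crack[nrow(crack) - 1, ])
  smax <- material$max_principal_stress

  ramp_cap <- load_cfg$ramp_cap
  ramp_step <- NULL
  onsets <- list()
  forced_run <- 0L
  stalled <- FALSE
  banned <- matrix(numeric(0), 0, 4)   # (row, col, drow, dcol) moves ruled out
  backtracks <- 0L
  best <- NULL                          # longest path seen during re-routing

  repeat {
    tip <- crack[nrow(crack), ]
    if (on_border(mesh, tip) || nrow(crack) > max_len) break

    # Mode-I: load normal to the crack direction at the tip. At pixel
    # resolution the tip direction is the smoothed one (the last few edges),
    # not the final 1-px segment, so staircase micro-turns do not starve a
    # pending macroscopic turn of its opening stress.
    kk0 <- nrow(crack)
    tdir <- unitv(crack[kk0, ] - crack[max(1, kk0 - 3), ])
    if (all(tdir == 0)) tdir <- tip_dir
    normal <- c(-tdir[2], tdir[1])
    ms <- split_nodes(mesh, crack)
    f <- patch_forces(ms, tip, tip_dir, normal,
                      load_cfg$patch_radius, load_cfg$patch_offset)
    if (is.null(f)) { stalled <- TRUE; break }
    sol <- solve_elasticity(ms, f)

    dirs <- forward_dirs(tip_dir)
    # Momentum: the mean direction of the last few edges. Elements behind the
    # momentum line sit beside or behind the freshly opened crack faces; the
    # bending of the strips there inflates their stress and would steer the
    # tip backwards into a parallel track, so only elements at or ahead of
    # the momentum front may drive growth.
    kk <- nrow(crack)
    mom4 <- crack[kk, ] - crack[max(1, kk - 4), ]
    if (!is.null(momentum_hint))
      mom4 <- mom4 + max(0, 4 - min(kk - 1, 4)) * momentum_hint
    momentum <- unitv(mom4)
    # over a longer scale the boundary inside one window is nearly straight:
    # a move turning more than ~120 degrees against the travel direction is
    # always the parallel-track artefact, never the groove. A short crack
    # (fresh seed) has little geometry of its own, so the caller's momentum
    # hint (the travel direction accumulated over previous windows) fills in.
    base <- max(1, kk - 10)
    mvec <- crack[kk, ] - crack[base, ]
    if (!is.null(momentum_hint)) mvec <- mvec + max(0, 10 - (kk - base)) * momentum_hint
    mlong <- unitv(mvec)
    score <- rep(-Inf, nrow(dirs))
    crit <- rep(NA_integer_, nrow(dirs))
    etype <- rep(2L, nrow(dirs))       # 0 groove wall, 1 groove middle, 2 full thickness
    eminh <- rep(Inf, nrow(dirs))      # depth of the deepest element beside the edge
    hthin <- min(mesh$h) + 0.3 * (max(mesh$h) - min(mesh$h))
    for (m in seq_len(nrow(dirs))) {
      nxt <- tip + dirs[m, ]
      if (nxt[1] < 0 || nxt[1] > mesh$nr || nxt[2] < 0 || nxt[2] > mesh$nc) next
      if (any(crack[, 1] == nxt[1] & crack[, 2] == nxt[2])) next  # keep path simple
      if (sum(dirs[m, ] * mlong) < -0.5) next
      if (nrow(banned) && any(banned[, 1] == tip[1] & banned[, 2] == tip[2] &
                              banned[, 3] == dirs[m, 1] & banned[, 4] == dirs[m, 2])) next
      # elements the move would expose: beside the new edge and around its
      # far node (the far-node ring keeps a groove that turns diagonally
      # across the tip neighbourhood visible)
      els <- unique(c(edge_elements(mesh, tip, nxt),
                      node_elements(mesh, nxt[1], nxt[2])))
      ei <- (els - 1L) %% mesh$nr + 1L
      ej <- (els - 1L) %/% mesh$nr + 1L
      fwd <- (ei - 0.5 - tip[1]) * momentum[1] + (ej - 0.5 - tip[2]) * momentum[2] >= -0.25
      els <- els[fwd]
      if (!length(els)) next
      b <- which.max(sol$sigma1[els])
      score[m] <- sol$sigma1[els[b]]
      crit[m] <- els[b]
      eh <- mesh$h[edge_elements(mesh, tip, nxt)]
      etype[m] <- c(2L, 0L, 1L)[sum(eh <= hthin) + 1L]
      eminh[m] <- min(eh)
    }
    # the crack follows the groove: an edge with no thin element beside it is
    # groove-free plate, which only the gap mechanism (stress concentration
    # carrying the tip over a few blank pixels) may cross
    score[etype == 2L] <- -Inf
    smax_unit <- max(score)
    onset <- if (is.finite(smax_unit) && smax_unit > 0) smax / smax_unit else Inf
    if (verbose) {
      lab <- apply(dirs, 1, paste, collapse = ",")
      message(sprintf("tip (%d,%d) dir (%d,%d) | %s | onset %.3g cap %.3g",
                      tip[1], tip[2], tip_dir[1], tip_dir[2],
                      paste(sprintf("[%s] %.3g", lab, score), collapse = "  "),
                      onset, if (is.null(ramp_cap)) NA else ramp_cap))
    }

    if (is.null(ramp_cap)) {             # calibrate on the seed configuration
      if (!is.finite(onset)) { stalled <- TRUE; break }
      ramp_cap <- load_cfg$ramp_safety * onset
    }
    ramp_step <- ramp_cap / load_cfg$ramp_steps

    k <- ceiling(onset / ramp_step - 1e-9)
    if (is.finite(onset) && k * ramp_step <= ramp_cap + 1e-9) {
      # fracture onset within the ramp: extend along the critical edge
      mbest <- which.max(score)
      th <- sol$theta[crit[mbest]]
      i <- (crit[mbest] - 1L) %% mesh$nr + 1L
      j <- (crit[mbest] - 1L) %/% mesh$nr + 1L
      ctr <- c(i - 0.5, j - 0.5)
      if (is.na(th)) {
        w <- tip_dir                     # isotropic critical state: continue straight
      } else {
        # principal direction in (row, col); the crack plane is perpendicular
        p <- c(sin(th), cos(th))
        w <- c(-p[2], p[1])
        al <- sum(w * tip_dir)
        if (abs(al) < 0.1) al <- sum(w * (ctr - tip))  # right-angle turn: towards the hot element
        if (al < 0) w <- -w
      }
      ok <- is.finite(score)
      # equal peak stress (a shared critical element) cannot resolve the
      # direction; the crack then follows the valley floor (deepest element
      # beside the new edge), then stays on the groove wall rather than
      # cutting the groove middle, and only then falls back to the
      # crack-plane direction
      key <- order(-round(score / smax_unit, 6), round(eminh, 1), etype,
                   -round(dirs %*% w, 6), -(dirs %*% tip_dir))
      mstar <- key[ok[key]][1]
      ext <- dirs[mstar, ]
      crack <- rbind(crack, tip + ext)
      tip_dir <- ext
      onsets[[length(onsets) + 1L]] <- c(k * ramp_step, 0)
      forced_run <- 0L
    } else {
      # ramp cap reached without extension: try to push across a short gap
      if (forced_run < gap_max) {
        nxt <- tip + tip_dir
        if (!any(abs(tip_dir) == 1) ||
            nxt[1] < 0 || nxt[1] > mesh$nr || nxt[2] < 0 || nxt[2] > mesh$nc ||
            any(crack[, 1] == nxt[1] & crack[, 2] == nxt[2])) {
          stalled <- TRUE
        } else {
          crack <- rbind(crack, nxt)
          onsets[[length(onsets) + 1L]] <- c(ramp_cap, 1)
          forced_run <- forced_run + 1L
          next
        }
      } else {
        stalled <- TRUE
      }
      if (stalled && forced_run > 0L) {
        # the forced probe never reconnected with a groove: retract it
        crack <- crack[seq_len(nrow(crack) - forced_run), , drop = FALSE]
        if (length(onsets) >= forced_run)
          onsets <- onsets[seq_len(length(onsets) - forced_run)]
        tip_dir <- unitv(crack[nrow(crack), ] - crack[nrow(crack) - 1, ])
        forced_run <- 0L
      }
      if (stalled && backtracks < max_backtracks && nrow(crack) > 2) {
        # dead end: undo the last free extension and rule that move out
        if (is.null(best) || nrow(crack) > nrow(best$crack))
          best <- list(crack = crack, onsets = onsets, tip_dir = tip_dir)
        last <- crack[nrow(crack), ]
        prev <- crack[nrow(crack) - 1, ]
        banned <- rbind(banned, c(prev, last - prev))
        crack <- crack[-nrow(crack), , drop = FALSE]
        if (length(onsets)) onsets <- onsets[-length(onsets)]
        tip_dir <- if (nrow(crack) >= 2) unitv(crack[nrow(crack), ] - crack[nrow(crack) - 1, ]) else tip_dir
        backtracks <- backtracks + 1L
        stalled <- FALSE
        next
      }
      break
    }
  }

  if (stalled && !is.null(best) && nrow(best$crack) > nrow(crack)) {
    # exploration ended short of the best route it found: report that one
    crack <- best$crack; onsets <- best$onsets; tip_dir <- best$tip_dir
  }
  ons <- if (length(onsets)) do.call(rbind, onsets) else matrix(numeric(0), 0, 2)
  new_crack_path(crack, tip_dir, stalled,
                 tibble::tibble(onset = ons[, 1], forced = ons[, 2] == 1),
                 ramp_cap, ramp_step)
}

new_crack_path <- function(vertices, tip_dir, stalled, onsets,
                           ramp_cap = NA_real_, ramp_step = NA_real_) {
  structure(list(vertices = vertices,
                 tip = vertices[nrow(vertices), ],
                 tip_direction = tip_dir,
                 stalled = stalled,
                 onsets = onsets,
                 ramp_cap = ramp_cap, ramp_step = ramp_step),
            class = "crack_path")
}

#' @export
print.crack_path <- function(x, ...) {
  cat(sprintf("<crack_path> %d vertices, tip (%g, %g), %s\n",
              nrow(x$vertices), x$tip[1], x$tip[2],
              if (x$stalled) "stalled" else "complete"))
  invisible(x)
}

#' Maximum principal stress versus groove depth
#'
#' Builds a family of plates of thickness `H` with a straight centred groove
#' of increasing depth, applies an identical distributed tension
#' perpendicular to the groove (bottom edge fixed, top edge pulled), and
#' reports the maximum principal stress for each depth. Deeper grooves
#' concentrate more stress, so the sequence increases strictly; depth 0
#' recovers the uniform far-field value.
#'
#' @param depths Nonnegative groove depths (strictly increasing), each
#'   `< H`.
#' @param H Plate thickness. Default 10.
#' @param n Plate size in elements (n x n). Default 21.
#' @param load Total applied force. Default 1.
#' @param material A [material_params()].
#' @return Tibble with columns `depth` and `max_sigma1`.
#' @export
groove_depth_stress_curve <- function(depths, H = 10, n = 21L, load = 1,
                                      material = material_params()) {
  if (any(diff(depths) <= 0) && length(depths) > 1)
    stop_param("`depths` must be strictly increasing")
  if (any(depths < 0 | depths >= H)) stop_param("depths must satisfy 0 <= depth < H")
  res <- vapply(depths, function(d) {
    th <- matrix(H, n, n)
    th[(n + 1) %/% 2, ] <- H - d
    mesh <- build_mesh(th, 1, material)
    bottom <- which(mesh$nodes[, 1] == n)
    top <- which(mesh$nodes[, 1] == 0)
    diri <- data.frame(node = rep(bottom, 2), dof = rep(c(1, 2), each = length(bottom)), value = 0)
    wt <- ifelse(mesh$nodes[top, 2] %in% c(0, n), 0.5, 1)
    forces <- data.frame(node = top, dof = 2, value = -load * wt / sum(wt))
    sol <- solve_elasticity(mesh, forces, diri)
    max(sol$sigma1)
  }, numeric(1))
  tibble::tibble(depth = depths, max_sigma1 = res)
}
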