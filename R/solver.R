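# Linear plane-stress finite elements on the structured plate mesh, and the
# discrete-crack mechanics: node splitting along the crack polyline makes the
# displacement field discontinuous across the crack faces.
#
# Geometry convention: node coordinates are stored as (row, col); inside the
# element routines the plane axes are x = col, y = row. The per-node degrees
# of freedom are (u_x, u_y) = (column displacement, row displacement),
# interleaved as dof = (2*node - 1, 2*node).

# 8x8 stiffness of a bilinear quad on [0, s]^2, unit thickness, plane stress.
element_stiffness <- function(E, nu, s = 1) {
  D <- E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
  gp <- c(-1, 1) / sqrt(3)
  K <- matrix(0, 8, 8)
  detJ <- (s / 2)^2
  for (xi in gp) for (eta in gp) {
    B <- bmat_at(xi, eta, s)
    K <- K + t(B) %*% D %*% B * detJ
  }
  K
}

# strain-displacement matrix at local coords (xi, eta) in [-1,1]^2
bmat_at <- function(xi, eta, s = 1) {
  dN <- rbind(c(-(1 - eta), (1 - eta), (1 + eta), -(1 + eta)),
              c(-(1 - xi), -(1 + xi), (1 + xi),  (1 - xi))) / 4
  dNx <- dN * (2 / s)  # J = (s/2) I
  B <- matrix(0, 3, 8)
  B[1, seq(1, 8, 2)] <- dNx[1, ]
  B[2, seq(2, 8, 2)] <- dNx[2, ]
  B[3, seq(1, 8, 2)] <- dNx[2, ]
  B[3, seq(2, 8, 2)] <- dNx[1, ]
  B
}

elasticity_matrix <- function(E, nu) {
  E / (1 - nu^2) * matrix(c(1, nu, 0, nu, 1, 0, 0, 0, (1 - nu) / 2), 3, 3)
}

#' Maximum principal stress of a plane-stress state
#'
#' Closed-form 2-D eigen-decomposition of the stress tensor. Also returns
#' the principal direction (angle of the sigma-1 eigenvector, in the
#' `x = col`, `y = row` frame). For an isotropic stress state the direction
#' is undefined and returned as `NA`; the crack propagator then continues
#' straight.
#'
#' @param sigma_xx,sigma_yy,tau_xy Stress components (vectorised).
#' @return List with `sigma1`, `sigma2` and `theta` (radians).
#' @export
principal_stress <- function(sigma_xx, sigma_yy, tau_xy) {
  ctr <- (sigma_xx + sigma_yy) / 2
  rad <- sqrt(((sigma_xx - sigma_yy) / 2)^2 + tau_xy^2)
  theta <- ifelse(rad < .Machine$double.eps * pmax(abs(ctr), 1),
                  NA_real_,
                  0.5 * atan2(2 * tau_xy, sigma_xx - sigma_yy))
  list(sigma1 = ctr + rad, sigma2 = ctr - rad, theta = theta)
}

#' Split mesh nodes along a crack polyline
#'
#' Duplicates every node strictly interior to the crack polyline so that the
#' two crack faces can separate: elements on opposite sides of the crack
#' reference opposite node copies, making the displacement field
#' discontinuous across the crack. The endpoints (the crack mouth and the
#' tip) remain shared, so the crack is closed at both ends and opens
#' elliptically in between, concentrating stress at the tip. This discrete
#' substitute for enrichment-based methods is exact at the pixel resolution
#' the contour is quantised to.
#'
#' @param mesh A [build_mesh()] result (unsplit).
#' @param crack Integer matrix (k x 2) of crack vertex `(row, col)` node
#'   coordinates; consecutive vertices must be 4-neighbours on the grid.
#' @return A new `plate_mesh` with duplicated nodes and a `split_info`
#'   data frame (`orig`, `dup`, `normal_row`, `normal_col`: the open-side
#'   normal of the duplicated copy).
#' @export
split_nodes <- function(mesh, crack) {
  stopifnot(inherits(mesh, "plate_mesh"))
  crack <- rbind(crack)
  k <- nrow(crack)
  if (k < 2) stop_input("crack must have at least 2 vertices")
  dd <- diff(crack)
  if (any(abs(dd) > 1) || any(rowSums(abs(dd)) != 1))
    rlang::abort("crack vertices must be consecutive mesh-edge neighbours",
                 class = c("crackseg_internal_error", "crackseg_error"))
  nr <- mesh$nr; nc <- mesh$nc
  e2n <- mesh$elem2node
  nodes <- mesh$nodes
  constrained <- mesh$constrained
  split_info <- NULL
  if (k >= 3) {
    elem_id <- function(i, j) (j - 1L) * nr + i   # expand.grid order: i fastest
    for (v in 2:(k - 1)) {
      r <- crack[v, 1]; c <- crack[v, 2]
      a1 <- atan2(crack[v - 1, 2] - c, crack[v - 1, 1] - r)  # to previous
      a2 <- atan2(crack[v + 1, 2] - c, crack[v + 1, 1] - r)  # to next
      if (a1 == a2) next  # degenerate backtrack; leave shared
      ei <- c(r, r, r + 1L, r + 1L); ej <- c(c, c + 1L, c, c + 1L)
      keep <- ei >= 1 & ei <= nr & ej >= 1 & ej <= nc
      ei <- ei[keep]; ej <- ej[keep]
      if (!length(ei)) next
      ang <- atan2(ej - 0.5 - c, ei - 0.5 - r)
      # side A: centroid angle in the CCW arc (a1 -> a2); side B: the rest
      arc <- (a2 - a1) %% (2 * pi)
      rel <- (ang - a1) %% (2 * pi)
      sideB <- rel > arc
      if (!any(sideB) || all(sideB)) next  # crack along the border; nothing to split
      vid <- node_id(r, c, nc)
      new_id <- nrow(nodes) + 1L
      nodes <- rbind(nodes, nodes[vid, , drop = FALSE])
      constrained <- c(constrained, constrained[vid])
      eidB <- elem_id(ei[sideB], ej[sideB])
      for (e in eidB) {
        hit <- e2n[e, ] == vid
        e2n[e, hit] <- new_id
      }
      # open-side normals: mean centroid offset of each copy's elements
      eidA <- elem_id(ei[!sideB], ej[!sideB])
      nA <- unitv(c(mean(ei[!sideB] - 0.5 - r), mean(ej[!sideB] - 0.5 - c)))
      nB <- unitv(c(mean(ei[sideB] - 0.5 - r), mean(ej[sideB] - 0.5 - c)))
      split_info <- rbind(split_info,
                          data.frame(orig = vid, dup = new_id,
                                     normal_row_orig = nA[1], normal_col_orig = nA[2],
                                     normal_row_dup = nB[1], normal_col_dup = nB[2]))
    }
  }
  out <- mesh
  out$nodes <- nodes
  out$elem2node <- e2n
  out$constrained <- constrained
  out$split_info <- split_info
  out
}

#' Solve the static plane-stress problem
#'
#' Assembles the variable-thickness stiffness matrix, applies Dirichlet
#' constraints, and solves for static equilibrium. Stresses are evaluated at
#' element centroids. The response is linear in the applied loads: doubling
#' every force doubles every displacement and stress exactly.
#'
#' @param mesh A `plate_mesh` (possibly node-split).
#' @param forces Either a full DOF force vector (length `2 * n_nodes`) or a
#'   data frame with columns `node`, `dof` (1 = x/col, 2 = y/row), `value`.
#' @param dirichlet Optional data frame `node`, `dof`, `value` of prescribed
#'   displacements. By default all DOFs of `mesh$constrained` nodes are fixed
#'   at zero; pass `dirichlet` to replace that set entirely.
#' @return List: `u` (n_nodes x 2 displacement matrix, columns x = col and
#'   y = row), `stress` (nelem x 3 matrix sigma_xx, sigma_yy, tau_xy),
#'   `sigma1`, `theta` (principal value/direction per element).
#' @export
solve_elasticity <- function(mesh, forces, dirichlet = NULL) {
  stopifnot(inherits(mesh, "plate_mesh"))
  nn <- nrow(mesh$nodes)
  ndof <- 2L * nn
  f <- numeric(ndof)
  if (is.data.frame(forces)) {
    idx <- 2L * forces$node - 2L + forces$dof
    f[idx] <- f[idx] + forces$value
  } else {
    if (length(forces) != ndof) stop_input("force vector has wrong length")
    f <- as.numeric(forces)
  }
  fixed_val <- numeric(ndof)
  is_fixed <- logical(ndof)
  if (is.null(dirichlet)) {
    is_fixed[rep(2L * which(mesh$constrained), each = 2L) - c(1L, 0L)] <- TRUE
  } else {
    idx <- 2L * dirichlet$node - 2L + dirichlet$dof
    is_fixed[idx] <- TRUE
    fixed_val[idx] <- dirichlet$value
  }
  if (!any(is_fixed)) stop_solver("no constrained DOFs: rigid-body modes present")

  mat <- mesh$material
  Ku <- element_stiffness(mat$youngs_modulus, mat$poisson_ratio, mesh$pixel_size)
  e2n <- mesh$elem2node
  nelem <- nrow(e2n)
  edof <- matrix(0L, nelem, 8L)
  edof[, seq(1, 8, 2)] <- 2L * e2n - 1L
  edof[, seq(2, 8, 2)] <- 2L * e2n
  ii <- rep(1:8, times = 8); jj <- rep(1:8, each = 8)
  rows <- as.vector(edof[, ii]); cols <- as.vector(edof[, jj])
  vals <- as.vector(outer(mesh$h, as.vector(Ku)))  # nelem x 64, h scales K
  K <- Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(ndof, ndof))

  free <- which(!is_fixed)
  rhs <- f[free] - as.numeric(K[free, is_fixed, drop = FALSE] %*% fixed_val[is_fixed])
  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  u <- fixed_val
  sol <- tryCatch(Matrix::solve(Kff, rhs),
                  error = function(e) stop_solver(paste("singular system:", conditionMessage(e))))
  u[free] <- as.numeric(sol)

  # centroid stresses, vectorised over elements
  B0 <- bmat_at(0, 0, mesh$pixel_size)
  D <- elasticity_matrix(mat$youngs_modulus, mat$poisson_ratio)
  Ue <- matrix(u[t(edof)], nrow = 8L)          # 8 x nelem
  S <- D %*% (B0 %*% Ue)                       # 3 x nelem
  ps <- principal_stress(S[1, ], S[2, ], S[3, ])
  list(u = matrix(u, ncol = 2L, byrow = TRUE),
       stress = t(S),
       sigma1 = ps$sigma1,
       theta = ps$theta)
}
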