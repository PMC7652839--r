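# Shared fixtures, generated in code at test time.

# small material with unit-friendly numbers for solver tests
test_material <- function(E = 1, nu = 0.3, smax = 1) {
  material_params(youngs_modulus = E, poisson_ratio = nu,
                  max_principal_stress = smax)
}

# distance from each (row, col) point to the nearest groove pixel centre
dist_to_groove <- function(vertices, thickness) {
  g <- which(unclass(thickness) < max(thickness), arr.ind = TRUE)
  ctr <- cbind(g[, 1] - 0.5, g[, 2] - 0.5)
  d2 <- outer(vertices[, 1], ctr[, 1], "-")^2 + outer(vertices[, 2], ctr[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}

# straight groove plate with an optional full-thickness gap in given columns
gap_groove_plate <- function(n = 31, H = 10, gap_cols = NULL) {
  gp <- gen_groove_plate(H = H, depth = H - 1, path = "straight", n = n)
  if (!is.null(gap_cols)) {
    mid <- (n + 1) %/% 2
    gp$thickness[mid, gap_cols] <- H
  }
  gp
}

# rectangular plate under uniform axial tension with symmetry rollers
uniform_tension_fixture <- function(nr = 10, nc = 20, t0 = 2, Ftot = 5,
                                    thickness = NULL) {
  mat <- test_material()
  th <- if (is.null(thickness)) matrix(t0, nr, nc) else thickness
  mesh <- build_mesh(th, 1, mat)
  left <- which(mesh$nodes[, 2] == 0)
  right <- which(mesh$nodes[, 2] == nc)
  diri <- data.frame(node = c(left, left[1]),
                     dof = c(rep(1, length(left)), 2), value = 0)
  wt <- ifelse(mesh$nodes[right, 1] %in% c(0, nr), 0.5, 1)
  forces <- data.frame(node = right, dof = 1, value = Ftot * wt / sum(wt))
  list(mesh = mesh, forces = forces, diri = diri, Ftot = Ftot, w = nr)
}

run_preset_lcpm <- function(name, seed = 1, config = lcpm_config()) {
  ph <- gen_phantom(phantom_preset(name, seed = seed))
  ps <- phantom_seed(ph)
  res <- run_lcpm(ph$image, config, center = ps$center, seed = ps$seed)
  list(phantom = ph, result = res,
       metrics = seg_metrics(res$mask, ph$mask),
       hd_truth = hausdorff(as.matrix(res$contour[, c("row", "col")]),
                            as.matrix(ph$boundary[, c("row", "col")])))
}
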