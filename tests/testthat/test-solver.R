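# Plane-stress FEM: analytic checks, principal stress, node splitting.

test_that("uniform tension reproduces sigma = F / (w t) exactly", {
  fx <- uniform_tension_fixture()
  sol <- solve_elasticity(fx$mesh, fx$forces, fx$diri)
  expect_equal(sol$stress[, 1], rep(fx$Ftot / (fx$w * 2), 200), tolerance = 1e-6)
  expect_lt(max(abs(sol$stress[, 2])), 1e-10)   # no transverse stress
})

test_that("patch test: a linear displacement field is reproduced exactly", {
  mesh <- build_mesh(matrix(3.7, 5, 10), 1, test_material())
  nd <- mesh$nodes; x <- nd[, 2]; y <- nd[, 1]
  ux <- 0.1 * x + 0.02 * y
  uy <- -0.03 * x + 0.05 * y
  b <- which(mesh$constrained)
  diri <- data.frame(node = rep(b, 2), dof = rep(c(1, 2), each = length(b)),
                     value = c(ux[b], uy[b]))
  sol <- solve_elasticity(mesh, numeric(2 * nrow(nd)), diri)
  expect_equal(sol$u[, 1], ux, tolerance = 1e-12)
  expect_equal(sol$u[, 2], uy, tolerance = 1e-12)
})

test_that("serial thickness step scales stress by the thickness ratio", {
  th <- matrix(1, 10, 20); th[, 1:10] <- 2
  fx <- uniform_tension_fixture(thickness = th)
  sol <- solve_elasticity(fx$mesh, fx$forces, fx$diri)
  thick <- mean(sol$stress[fx$mesh$elem_ij[, 2] %in% 3:6, 1])
  thin <- mean(sol$stress[fx$mesh$elem_ij[, 2] %in% 15:18, 1])
  expect_equal(thin / thick, 2, tolerance = 0.02)
})

test_that("response is exactly linear in the load", {
  fx <- uniform_tension_fixture()
  s1 <- solve_elasticity(fx$mesh, fx$forces, fx$diri)
  f2 <- fx$forces; f2$value <- 2 * f2$value
  s2 <- solve_elasticity(fx$mesh, f2, fx$diri)
  expect_equal(s2$stress, 2 * s1$stress, tolerance = 1e-12)
  expect_equal(s2$u, 2 * s1$u, tolerance = 1e-12)
})

test_that("solver rejects an unconstrained system", {
  mesh <- build_mesh(matrix(1, 4, 4), 1, test_material())
  expect_error(solve_elasticity(mesh, numeric(2 * nrow(mesh$nodes)),
                                dirichlet = data.frame(node = integer(),
                                                       dof = integer(),
                                                       value = numeric())),
               class = "crackseg_solver_error")
})

test_that("principal stress closed form", {
  p <- principal_stress(3, 1, 0)
  expect_equal(p$sigma1, 3)
  expect_equal(p$theta %% pi, 0)
  p2 <- principal_stress(0, 0, 1)
  expect_equal(p2$sigma1, 1)
  expect_equal(abs(p2$theta), pi / 4)
  p3 <- principal_stress(2, 2, 0)  # isotropic: direction undefined
  expect_equal(p3$sigma1, 2)
  expect_true(is.na(p3$theta))
  # sigma1 >= sigma2 on random states
  set.seed(5)
  ps <- principal_stress(rnorm(50), rnorm(50), rnorm(50))
  expect_true(all(ps$sigma1 >= ps$sigma2))
})

test_that("node splitting duplicates interior crack vertices only", {
  mesh <- build_mesh(matrix(1, 10, 10), 1, test_material())
  crack <- cbind(5, 2:7)                 # 5 segments, 4 interior vertices
  ms <- split_nodes(mesh, crack)
  expect_equal(nrow(ms$nodes) - nrow(mesh$nodes), 4)

  # zero-interior crack leaves the node count unchanged
  ms0 <- split_nodes(mesh, cbind(5, 2:3))
  expect_equal(nrow(ms0$nodes), nrow(mesh$nodes))

  expect_error(split_nodes(mesh, rbind(c(5, 2), c(7, 4))),
               class = "crackseg_internal_error")
})

test_that("an opening load separates the split crack faces", {
  mesh <- build_mesh(matrix(1, 10, 10), 1, test_material())
  ms <- split_nodes(mesh, cbind(5, 2:7))
  up <- crackseg:::node_id(4, 4, 10)
  dn <- crackseg:::node_id(6, 4, 10)
  f <- data.frame(node = c(dn, up), dof = 2, value = c(3, -3))
  sol <- solve_elasticity(ms, f)
  si <- ms$split_info
  gap <- (sol$u[si$dup, 2] - sol$u[si$orig, 2]) *
    sign(si$normal_row_dup - si$normal_row_orig)
  expect_true(all(gap > 0))  # faces move apart along their outward normals
})
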