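# Crack growth through grooved plates.

test_that("the crack follows a straight groove to the far border", {
  gp <- gen_groove_plate(10, 9, "straight", n = 31)
  mesh <- build_mesh(gp$thickness, 1, material_params())
  cp <- propagate_crack(mesh, gp$seed_points, load_cfg = load_spec())
  expect_false(cp$stalled)
  expect_gte(max(cp$vertices[, 2]), 30)
  expect_true(all(dist_to_groove(cp$vertices, gp$thickness) <= 1))
})

test_that("a uniform plate under a capped ramp stalls without extension", {
  mesh <- build_mesh(matrix(10, 31, 31), 1, material_params())
  cp <- propagate_crack(mesh, cbind(16, 2:5),
                        load_cfg = load_spec(ramp_cap = 1), gap_max = 0)
  expect_true(cp$stalled)
  expect_equal(nrow(cp$vertices), 4)   # the seed, unchanged
})

test_that("the crack traces a quarter-arc groove", {
  gp <- gen_groove_plate(10, 9, "arc", n = 31)
  mesh <- build_mesh(gp$thickness, 1, material_params())
  cp <- propagate_crack(mesh, gp$seed_points, load_cfg = load_spec())
  expect_false(cp$stalled)
  d <- dist_to_groove(cp$vertices, gp$thickness)
  expect_lt(mean(d), 1)
  expect_gte(mean(d <= 1), 0.95)
})

test_that("short gaps are crossed, wide gaps stall the front", {
  g3 <- gap_groove_plate(gap_cols = 14:16)
  cp3 <- propagate_crack(build_mesh(g3$thickness, 1, material_params()),
                         g3$seed_points, load_cfg = load_spec())
  expect_false(cp3$stalled)
  expect_gte(max(cp3$vertices[, 2]), 30)
  expect_equal(sum(cp3$onsets$forced), 3)  # exactly the gap pixels forced

  g8 <- gap_groove_plate(gap_cols = 12:19)
  cp8 <- propagate_crack(build_mesh(g8$thickness, 1, material_params()),
                         g8$seed_points, load_cfg = load_spec())
  expect_true(cp8$stalled)
  expect_lte(max(cp8$vertices[, 2]), 12)   # stopped at the gap, probe retracted
  expect_true(all(dist_to_groove(cp8$vertices, g8$thickness) <= 1))
})

test_that("maximum stress grows strictly with groove depth", {
  curve <- groove_depth_stress_curve(c(0, 2, 4, 6, 8), H = 10, n = 21)
  expect_true(all(diff(curve$max_sigma1) > 0))
  # depth 0: homogeneous plate, max equals the far-field level (no hot spot)
  flat <- curve$max_sigma1[1]
  expect_lt(max(curve$max_sigma1[1]) / flat, 1.001)
  # determinism
  curve2 <- groove_depth_stress_curve(c(0, 2, 4, 6, 8), H = 10, n = 21)
  expect_identical(curve$max_sigma1, curve2$max_sigma1)
})

test_that("detected onset matches the linear-scaling prediction", {
  gp <- gen_groove_plate(10, 9, "straight", n = 21)
  mat <- material_params()
  mesh <- build_mesh(gp$thickness, 1, mat)
  cap <- 1e10
  cp <- propagate_crack(mesh, gp$seed_points,
                        load_cfg = load_spec(ramp_cap = cap, ramp_steps = 50))
  # oracle: unit-load solve of the seed configuration
  seed <- gp$seed_points
  ms <- split_nodes(mesh, seed)
  tip <- seed[nrow(seed), ]
  tip_dir <- tip - seed[nrow(seed) - 1, ]
  f <- crackseg:::patch_forces(ms, tip, tip_dir, c(-tip_dir[2], tip_dir[1]), 3, 2)
  sol <- solve_elasticity(ms, f)
  els <- unique(c(crackseg:::edge_elements(mesh, tip, tip + tip_dir),
                  crackseg:::node_elements(mesh, tip[1] + tip_dir[1],
                                           tip[2] + tip_dir[2])))
  onset_pred <- mat$max_principal_stress / max(sol$sigma1[els])
  step <- cap / 50
  expect_lte(abs(cp$onsets$onset[1] - onset_pred), step)
})

test_that("crack growth is deterministic", {
  gp <- gen_groove_plate(10, 9, "spline", n = 31, seed = 4)
  mesh <- build_mesh(gp$thickness, 1, material_params())
  cp1 <- propagate_crack(mesh, gp$seed_points, load_cfg = load_spec())
  cp2 <- propagate_crack(mesh, gp$seed_points, load_cfg = load_spec())
  expect_identical(cp1$vertices, cp2$vertices)
  expect_identical(cp1$onsets, cp2$onsets)
})
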