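# Synthetic phantom generator: determinism, geometry, noise, gaps.

test_that("phantoms are reproducible and masks match analytic areas", {
  sp <- phantom_spec("disk", size = 128, r = 30)
  p1 <- gen_phantom(sp)
  p2 <- gen_phantom(sp)
  expect_identical(p1$image, p2$image)
  expect_identical(p1$mask, p2$mask)
  expect_lt(abs(sum(p1$mask) - pi * 30^2) / (pi * 30^2), 0.01)

  pn1 <- gen_phantom(phantom_spec("blob", noise_sd = 0.05, seed = 9))
  pn2 <- gen_phantom(phantom_spec("blob", noise_sd = 0.05, seed = 9))
  expect_identical(pn1$image, pn2$image)
})

test_that("noise and gaps never change the truth mask", {
  base <- gen_phantom(phantom_spec("ellipse", seed = 2))
  noisy <- gen_phantom(phantom_spec("ellipse", seed = 2, noise_sd = 0.08))
  gapped <- gen_phantom(phantom_spec("ellipse", seed = 2,
                                     gaps = list(c(45, 20))))
  expect_identical(base$mask, noisy$mask)
  expect_identical(base$mask, gapped$mask)
})

test_that("a gap erases the local edge gradient", {
  g1 <- gaussian_gradient(gen_phantom(
    phantom_spec("disk", r = 30, gaps = list(c(0, 10))))$image, 1.5,
    squared = FALSE)
  g0 <- gaussian_gradient(gen_phantom(phantom_spec("disk", r = 30))$image, 1.5,
                          squared = FALSE)
  b <- gen_phantom(phantom_spec("disk", r = 30))$boundary
  dang <- abs(((b$theta + pi) %% (2 * pi)) - pi)
  on_arc <- dang <= 5 * pi / 180
  far <- dang > 30 * pi / 180
  on_idx <- cbind(round(b$row[on_arc]), round(b$col[on_arc]))
  far_idx <- cbind(round(b$row[far]), round(b$col[far]))
  expect_lte(mean(g1[on_idx]), 0.05 * mean(g0[far_idx]))
})

test_that("additive noise has the declared distribution", {
  img <- matrix(0.5, 128, 128)
  expect_identical(gen_noise(img, 0, 1), img)
  n1 <- gen_noise(img, 0.05, 1)
  expect_true(sd(n1 - img) > 0.045 && sd(n1 - img) < 0.055)
  n2 <- gen_noise(img, 0.05, 2)
  expect_false(identical(n1, n2))
  se <- 0.05 / sqrt(length(img))
  expect_lt(abs(mean(n1) - mean(n2)), 3 * sqrt(2) * se)
})

test_that("groove plates carve the stated depth along each path type", {
  gs <- gen_groove_plate(10, 9, "straight", n = 21)
  expect_true(all(gs$thickness[gs$groove] == 1))
  expect_true(all(gs$thickness[-((gs$groove[, 2] - 1) * 21 + gs$groove[, 1])] == 10))

  ga <- gen_groove_plate(10, 5, "arc", n = 31)
  expect_true(all(ga$thickness[ga$groove] == 5))
  # groove pixels hug the analytic arc
  ctr <- cbind(ga$groove[, 1] - 0.5, ga$groove[, 2] - 0.5)
  d <- abs(sqrt(ctr[, 1]^2 + ctr[, 2]^2) - 0.65 * 31)
  expect_lt(max(d), 0.8)

  g0 <- gen_groove_plate(10, 0, "straight", n = 15)
  expect_true(all(g0$thickness == 10))
  expect_error(gen_groove_plate(10, 10), class = "crackseg_parameter_error")

  # spline grooves are reproducible from the seed
  s1 <- gen_groove_plate(10, 9, "spline", n = 31, seed = 3)
  s2 <- gen_groove_plate(10, 9, "spline", n = 31, seed = 3)
  expect_identical(unclass(s1$thickness), unclass(s2$thickness))
})

test_that("blob radii stay within the declared perturbation band", {
  for (s in 1:5) {
    sp <- phantom_spec("blob", r = 30, blob_amp = 0.12, seed = s)
    rads <- crackseg:::phantom_radius(sp, seq(0, 2 * pi, length.out = 360))
    expect_true(all(rads >= 30 * (1 - 0.125) & rads <= 30 * (1 + 0.125)))
  }
})
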