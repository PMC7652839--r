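# Intensity transforms: gradient, negative rescale, gamma.

test_that("gaussian gradient vanishes on constant images and peaks on edges", {
  expect_equal(max(abs(gaussian_gradient(matrix(0.5, 16, 16), 1.5))), 0,
               tolerance = 1e-30)

  # vertical step edge: per-row maximum within 1 px of the edge
  s <- matrix(0, 40, 60); s[, 30:60] <- 1
  g <- gaussian_gradient(s, 1)
  peaks <- apply(g[5:35, ], 1, which.max)
  expect_true(all(abs(peaks - 29.5) <= 1))

  # oracle: central finite difference of the smoothed image agrees on the
  # peak location
  gs <- gaussian_gradient(s, 1, method = "smooth_diff")
  peaks2 <- apply(gs[5:35, ], 1, which.max)
  expect_equal(peaks, peaks2)
})

test_that("derivative-of-Gaussian and smooth-then-differentiate agree", {
  set.seed(42)
  x <- matrix(runif(64 * 64), 64, 64)
  a <- gaussian_gradient(x, 1.5, method = "dog")
  b <- gaussian_gradient(x, 1.5, method = "smooth_diff")
  expect_lt(max(abs(a - b)), 1e-8)
})

test_that("gradient errors on bad input", {
  expect_error(gaussian_gradient(matrix(0, 10, 10), -1), class = "crackseg_parameter_error")
  expect_error(gaussian_gradient(matrix(0, 2, 2), 1), class = "crackseg_input_error")
})

test_that("negative rescale maps extremes and flags degenerate windows", {
  out <- negative_rescale(matrix(c(0, 10, 5, 5), 2, 2))
  expect_equal(out, matrix(c(1, 0, 0.5, 0.5), 2, 2), ignore_attr = TRUE)

  set.seed(7)
  x <- matrix(rexp(100), 10, 10)
  y <- negative_rescale(x)
  expect_equal(min(y), 0)
  expect_equal(max(y), 1)
  expect_false(is_degenerate(y))

  # already spanning [0,1]: exact complement
  z <- matrix(seq(0, 1, length.out = 25), 5, 5)
  expect_equal(negative_rescale(z), 1 - z, ignore_attr = TRUE)

  d <- negative_rescale(matrix(3, 4, 4))
  expect_true(is_degenerate(d))
  expect_true(all(d == 1))
})

test_that("power transform is the elementwise power with fixed endpoints", {
  expect_equal(power_transform(matrix(0.5, 1, 1), 2)[1], 0.25)
  x <- matrix(seq(0, 1, length.out = 16), 4, 4)
  expect_equal(unclass(power_transform(x, 1)), unclass(x), ignore_attr = TRUE)
  # gamma = 3 stretches high-value ratios: (0.8/0.2)^3 = 64 > 4
  y <- power_transform(matrix(c(0.2, 0.8), 1, 2), 3)
  expect_equal(y[2] / y[1], 64)
  expect_gt(y[2] / y[1], 0.8 / 0.2)
  expect_error(power_transform(x, 0), class = "crackseg_parameter_error")
})

test_that("rank order and range are preserved through the enhancement chain", {
  set.seed(11)
  for (gam in c(0.4, 1, 2.5)) {
    x <- matrix(runif(81), 9, 9)
    y <- enhance_gradient(x, gam)
    expect_true(all(y >= 0 & y <= 1))
    expect_equal(order(as.vector(power_transform(x, gam))), order(as.vector(x)))
  }
})

test_that("the enhanced-image minimum marks a sharp edge to within a pixel", {
  ph <- gen_phantom(phantom_spec("disk", size = 64, r = 20))
  g <- gaussian_gradient(ph$image, 1.5)
  en <- enhance_gradient(g, 2)
  w <- which(en == min(en), arr.ind = TRUE)[1, ]
  d <- sqrt(sum((w - ph$spec$center)^2))
  expect_lt(abs(d - 20), 1)
})
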