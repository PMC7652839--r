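# LCPM driver pieces and one full segmentation.

test_that("crack vertices translate from window to image coordinates", {
  img <- matrix(runif(100 * 100), 100, 100)
  w <- extract_window(img, window_spec(c(50, 50), 10))
  lb <- crack_to_boundary(cbind(10, 15), w)
  expect_equal(c(lb$row, lb$col), c(50, 55))

  # a crack spanning the window maps to opposite window borders
  verts <- cbind(10, 0:21)
  lb2 <- crack_to_boundary(verts, w)
  expect_equal(range(lb2$col), c(40, 61))
  expect_error(crack_to_boundary(matrix(numeric(0), 0, 2), w),
               class = "crackseg_input_error")
})

test_that("boundary direction fitting is orthogonal and vertical-safe", {
  p45 <- cbind(1:10, 1:10)               # row = col: 45 degrees
  expect_equal(fit_boundary_direction(p45)$theta, pi / 4)

  vert <- cbind(1:10, rep(5, 10))        # constant col: vertical line
  expect_equal(abs(fit_boundary_direction(vert)$theta), pi / 2)

  set.seed(31)
  noisy <- cbind(rnorm(20, 0, 0.3), seq(1, 20))
  expect_lt(abs(fit_boundary_direction(noisy)$theta), 5 * pi / 180)

  # TLS oracle: first eigenvector of the covariance
  set.seed(8)
  P <- cbind(rnorm(30), rnorm(30) * 3)
  v <- eigen(cov(P))$vectors[, 1]
  want <- atan2(v[1], v[2])
  if (want <= -pi / 2) want <- want + pi
  if (want > pi / 2) want <- want - pi
  expect_equal(fit_boundary_direction(P)$theta, want, tolerance = 1e-8)

  expect_error(fit_boundary_direction(rbind(c(2, 2), c(2, 2))),
               class = "crackseg_input_error")
})

test_that("centre update steps exactly alpha along the fitted direction", {
  expect_equal(next_center(c(50, 50), 0, 8, c(0, 1)), c(50, 58))
  expect_equal(next_center(c(50, 50), 0, 8, c(0, -1)), c(50, 42))
  set.seed(2)
  for (k in 1:20) {
    th <- runif(1, -pi / 2, pi / 2)
    a <- runif(1, 1, 20)
    ps <- c(sin(th), cos(th)) * sample(c(-1, 1), 1)
    nc <- next_center(c(10, 10), th, a, ps)
    expect_equal(sqrt(sum((nc - c(10, 10))^2)), a, tolerance = 1e-12)
    expect_gte(sum((nc - c(10, 10)) * ps), 0)
  }
  expect_error(next_center(c(0, 0), 0, -1, c(1, 0)), class = "crackseg_parameter_error")
})

test_that("merge deduplicates overlap, bridges ends, and preserves endpoints", {
  fr <- tibble::tibble(row = c(1, 1, 1, 1, 1, 1), col = c(1, 2, 3, 3, 4, 5),
                       window = c(1L, 1L, 1L, 2L, 2L, 2L))
  m <- merge_and_smooth(fr, smooth_window = 1)
  expect_equal(nrow(m), 5)              # duplicate (1,3) collapsed

  # two fronts ending 2 px apart are joined into a closed loop
  sq <- tibble::tibble(row = c(0, 0, 0, 5, 10, 10, 10, 5, 2),
                       col = c(0, 5, 10, 10, 10, 5, 0, 0, 0),
                       window = 1:9)
  mc <- merge_and_smooth(sq, closed = TRUE, smooth_window = 1)
  expect_true(attr(mc, "closed"))
  gapd <- sqrt(sum((c(mc$row[1], mc$col[1]) -
                    c(mc$row[nrow(mc)], mc$col[nrow(mc)]))^2))
  expect_lte(gapd, 1.5)

  # smoothing leaves open-contour endpoints untouched
  op <- tibble::tibble(row = c(0, 1, 0, 1, 0, 1, 0), col = 0:6, window = 1L)
  ms <- merge_and_smooth(op, smooth_window = 5)
  expect_equal(c(ms$row[1], ms$col[1]), c(0, 0))
  expect_equal(c(ms$row[nrow(ms)], ms$col[nrow(ms)]), c(0, 6))
  # interior is smoothed
  expect_lt(max(abs(ms$row[3:5] - 0.5)), 0.45)
})

test_that("closed contours come out counter-clockwise", {
  # clockwise square in (x = col, y = -row) terms
  sq <- tibble::tibble(row = c(0, 5, 5, 0), col = c(0, 0, 5, 5), window = 1L)
  m <- merge_and_smooth(sq, closed = TRUE, smooth_window = 1)
  x <- m$col; y <- -m$row
  area <- sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y) / 2
  expect_gt(area, 0)
})

test_that("a clean disk is segmented closed with high overlap", {
  out <- run_preset_lcpm("textured")    # disk + mild texture
  expect_true(out$result$closed)
  expect_gte(out$metrics$dsc, 0.97)
  expect_lte(out$hd_truth, 3)
  expect_equal(out$result$fronts, 1)
  expect_equal(out$result$stalls, 0)

  # every consecutive window pair keeps the running crack end inside the
  # next window (the seed hand-off invariant)
  w <- out$result$windows
  expect_true(all(diff(w$window) == 1))
  expect_true(all(w$n_new[-1] > 0))
})

test_that("an invisible boundary arc is bridged and the contour closes", {
  out <- run_preset_lcpm("gapped")
  expect_true(out$result$closed)
  expect_gte(out$metrics$dsc, 0.95)
  expect_gte(out$result$fronts, 2)     # wide gap: a second front was needed
})

test_that("random ellipses close with high overlap", {
  dscs <- c(); hds <- c(); closed <- c()
  for (s in 1:6) {
    set.seed(100 + s)
    axes <- runif(2, 20, 34)
    rot <- runif(1, 0, pi)
    ph <- gen_phantom(phantom_spec("ellipse", axes = axes, rotation = rot,
                                   seed = s))
    ps <- phantom_seed(ph)
    res <- run_lcpm(ph$image, lcpm_config(), center = ps$center, seed = ps$seed)
    m <- seg_metrics(res$mask, ph$mask)
    closed <- c(closed, res$closed)
    dscs <- c(dscs, m$dsc)
    hds <- c(hds, hausdorff(as.matrix(res$contour[, c("row", "col")]),
                            as.matrix(ph$boundary[, c("row", "col")])))
  }
  expect_true(all(closed))
  expect_gte(mean(dscs), 0.95)
  expect_lte(mean(hds), 3)
})

test_that("tidy and glance summarise a result", {
  out <- run_preset_lcpm("inhomog_obj")
  td <- tidy(out$result)
  expect_true(all(c("row", "col", "window") %in% names(td)))
  gl <- glance(out$result)
  expect_equal(nrow(gl), 1)
  expect_true(gl$closed)
  expect_gt(gl$area, 1000)
})
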