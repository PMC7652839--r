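# Initial-crack construction: sweep geometry, Canny, automatic seeding.

test_that("sweep angle geometry matches the apex formula", {
  sw <- sweep_angles(1, 2)
  expect_equal(sw$phi, 2 * atan(0.5))
  expect_equal(sw$angles, c(0, sw$phi / 2, sw$phi))

  # large-N asymptotics: phi * N -> 1
  for (N in c(50, 200, 1000)) {
    expect_equal(sweep_angles(N, 4)$phi * N, 1, tolerance = 1 / N)
  }

  # strictly increasing, spanning [0, phi]
  sw2 <- sweep_angles(2.5, 7)
  expect_true(all(diff(sw2$angles) > 0))
  expect_equal(range(sw2$angles), c(0, sw2$phi))

  expect_error(sweep_angles(0.5, 4), class = "crackseg_parameter_error")
  expect_error(sweep_angles(2, 1), class = "crackseg_parameter_error")
})

test_that("automatic seeding lands on a straight edge", {
  w <- matrix(0.2, 31, 31); w[, 16:31] <- 0.8   # vertical edge at col 15.5
  seed <- auto_initial_crack(w)
  expect_s3_class(seed, "crack_seed")
  expect_true(all(abs(seed$points[, 2] - 15.5) <= 1.5))
  # direction within 10 degrees of vertical
  d <- seed$points[2, ] - seed$points[1, ]
  ang <- abs(atan2(d[2], d[1]))               # 0 = along rows (vertical edge)
  expect_lt(min(ang, pi - ang), 10 * pi / 180)
})

test_that("automatic seeding tracks edges at arbitrary orientation", {
  for (deg in c(20, 65, 120, 160)) {
    a <- deg * pi / 180
    n <- 31
    rr <- matrix(seq_len(n), n, n); cc <- t(rr)
    w <- ifelse((rr - 16) * sin(a) + (cc - 16) * cos(a) > 0, 0.8, 0.2)
    seed <- auto_initial_crack(w)
    d <- seed$points[2, ] - seed$points[1, ]
    got <- atan2(d[1], d[2])
    want <- atan2(-cos(a), sin(a))            # edge direction
    diff <- abs(((got - want + pi / 2) %% pi) - pi / 2)
    expect_lt(diff, 10 * pi / 180)
  }
})

test_that("blank windows raise seed-not-found", {
  expect_error(auto_initial_crack(matrix(0.5, 31, 31)),
               class = "crackseg_seed_not_found")
})

test_that("automatic seed chord stays within a pixel of a circular arc", {
  ph <- gen_phantom(phantom_spec("disk", size = 64, r = 22))
  w <- extract_window(ph$image, window_spec(c(32, 10), 12))
  seed <- auto_initial_crack(w)
  off <- c(attr(w, "rows")[1], attr(w, "cols")[1])
  pts <- sweep(seed$points, 2, -off)
  d <- sqrt((pts[, 1] - ph$spec$center[1])^2 + (pts[, 2] - ph$spec$center[2])^2)
  expect_true(all(abs(d - 22) <= 1.5))
})

test_that("manual seeds are validated and deduplicated", {
  s <- manual_initial_crack(rbind(c(10, 10), c(10, 13)))
  expect_equal(nrow(s$points), 2)
  expect_equal(s$source, "manual")
  expect_error(manual_initial_crack(rbind(c(5, 5))), class = "crackseg_input_error")
  expect_warning(s2 <- manual_initial_crack(rbind(c(1, 1), c(1, 1), c(2, 1))),
                 "duplicate")
  expect_equal(nrow(s2$points), 2)
  expect_error(suppressWarnings(manual_initial_crack(rbind(c(1, 1), c(1, 1)))),
               class = "crackseg_input_error")
})

test_that("canny marks a step edge thinly and hysteresis links weak pixels", {
  w <- matrix(0.1, 25, 25); w[, 13:25] <- 0.9
  e <- canny_edges(w, sigma = 1.5)
  hit <- which(e, arr.ind = TRUE)
  expect_true(nrow(hit) >= 15)
  expect_true(all(abs(hit[, 2] - 12.5) <= 1.5))  # thin response at the edge
})
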