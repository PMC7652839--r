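# Segmentation metrics against brute-force oracles.

brute_dice <- function(a, b) {
  inter <- 0; na <- 0; nb <- 0
  for (i in seq_len(nrow(a))) for (j in seq_len(ncol(a))) {
    if (a[i, j] && b[i, j]) inter <- inter + 1
    if (a[i, j]) na <- na + 1
    if (b[i, j]) nb <- nb + 1
  }
  2 * inter / (na + nb)
}

brute_hausdorff <- function(A, B) {
  h <- 0
  for (i in seq_len(nrow(A))) {
    best <- Inf
    for (j in seq_len(nrow(B)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    h <- max(h, best)
  }
  for (j in seq_len(nrow(B))) {
    best <- Inf
    for (i in seq_len(nrow(A)))
      best <- min(best, sqrt(sum((A[i, ] - B[j, ])^2)))
    h <- max(h, best)
  }
  h
}

test_that("dice handles the canonical cases", {
  a <- matrix(FALSE, 4, 4); a[1:2, 1:2] <- TRUE
  expect_equal(dice(a, a), 1)
  b <- matrix(FALSE, 4, 4); b[3:4, 3:4] <- TRUE
  expect_equal(dice(a, b), 0)
  c2 <- matrix(FALSE, 4, 4); c2[2:3, 1:2] <- TRUE  # |A|=|B|=4, overlap 2
  expect_equal(dice(a, c2), 0.5)
  expect_warning(d0 <- dice(matrix(FALSE, 2, 2), matrix(FALSE, 2, 2)))
  expect_equal(d0, 1)
})

test_that("metrics agree with brute-force double loops on random masks", {
  set.seed(123)
  for (k in 1:25) {
    a <- matrix(runif(64) > 0.6, 8, 8)
    b <- matrix(runif(64) > 0.6, 8, 8)
    if (sum(a) + sum(b) == 0) next
    expect_equal(dice(a, b), brute_dice(a, b))
    tf <- tnr_fpr(a, b)
    bg <- !b
    expect_equal(tf$tnr, sum(bg & !a) / sum(bg))
    expect_identical(tf$tnr + tf$fpr, 1)
  }
  for (k in 1:25) {
    A <- matrix(runif(12, 0, 20), ncol = 2)
    B <- matrix(runif(16, 0, 20), ncol = 2)
    expect_equal(hausdorff(A, B), brute_hausdorff(A, B))
  }
})

test_that("hausdorff basics, units, and metric axioms", {
  P <- cbind(c(1, 5, 9), c(2, 2, 2))
  expect_equal(hausdorff(P, P), 0)
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4))), 5)
  expect_equal(hausdorff(rbind(c(0, 0)), rbind(c(3, 4)), spacing = 2), 10)
  expect_error(hausdorff(P, matrix(numeric(0), 0, 2)), class = "crackseg_input_error")
  # symmetry and triangle inequality on random triples
  set.seed(9)
  for (k in 1:10) {
    A <- matrix(runif(10, 0, 10), ncol = 2)
    B <- matrix(runif(8, 0, 10), ncol = 2)
    C <- matrix(runif(12, 0, 10), ncol = 2)
    expect_equal(hausdorff(A, B), hausdorff(B, A))
    expect_lte(hausdorff(A, C), hausdorff(A, B) + hausdorff(B, C) + 1e-12)
  }
})

test_that("tnr/fpr counting on a small mask", {
  ref <- matrix(FALSE, 4, 4); ref[1:2, 1:4] <- TRUE   # 8 background px
  pred <- ref; pred[3, 1:2] <- TRUE                   # 2 background marked
  tf <- tnr_fpr(pred, ref)
  expect_equal(tf$tnr, 0.75)
  expect_equal(tf$fpr, 0.25)
  expect_error(tnr_fpr(pred, matrix(TRUE, 4, 4)), class = "crackseg_input_error")
})

test_that("dice decreases as symmetric difference grows", {
  a <- matrix(FALSE, 10, 10); a[3:7, 3:7] <- TRUE
  prev <- 1
  b <- a
  set.seed(21)
  flips <- which(!a)[sample(sum(!a), 10)]
  for (f in flips) {
    b[f] <- TRUE
    cur <- dice(a, b)
    expect_lte(cur, prev)
    prev <- cur
  }
})

test_that("contour rasterisation fills a disk (rim pixels count as interior)", {
  ph <- gen_phantom(phantom_spec("disk", size = 128, r = 30))
  b <- ph$boundary
  ct <- tibble::tibble(row = b$row, col = b$col)
  attr(ct, "closed") <- TRUE
  m <- contour_mask(ct, c(128, 128))
  # the rim band inflates the area by about half a pixel times the perimeter
  expect_lt(abs(sum(m) - pi * 30^2) / (pi * 30^2), 0.05)
  expect_gte(sum(m), pi * 30^2 - 1)     # never smaller than the true disk
  expect_gt(dice(m, ph$mask), 0.97)
})

test_that("mask outline is the 8-connected rim", {
  m <- matrix(FALSE, 7, 7); m[3:5, 3:5] <- TRUE
  o <- mask_outline(m)
  expect_equal(nrow(o), 8)                 # 3x3 block minus its centre
  expect_false(any(o[, 1] == 4 & o[, 2] == 4))
})
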