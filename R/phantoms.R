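# Synthetic phantoms with analytic ground truth, reproducing the test
# regimes the method is meant to handle: inhomogeneous backgrounds and
# objects, texture, Gaussian noise, and boundary gaps (invisible arcs).

#' Specify a synthetic phantom
#'
#' A phantom is an object (disk, ellipse, or Fourier-perturbed blob) on a
#' background, with optional intensity inhomogeneity, texture, additive
#' Gaussian noise, and boundary gaps. Gaps erase the local edge contrast by
#' blending the object into the background over an angular sector, without
#' changing the ground-truth mask: the boundary still exists, it is just
#' invisible there.
#'
#' @param shape `"disk"`, `"ellipse"` or `"blob"`.
#' @param size Image side in pixels (square). Default 128.
#' @param center Object centre `(row, col)`; default image centre.
#' @param r Disk/blob base radius (px). Default 30.
#' @param axes Ellipse semi-axes `(a_row, a_col)`. Default `c(24, 34)`.
#' @param rotation Ellipse rotation (radians). Default 0.
#' @param blob_amp Maximum relative amplitude of the blob's radial Fourier
#'   perturbation (harmonics up to 5). Default 0.12.
#' @param intensity `"uniform"`, `"ramp"` (linear background ramp) or
#'   `"radial"` (radially inhomogeneous object).
#' @param object_level,background_level Base intensities. Defaults 0.30 and
#'   0.70.
#' @param texture `"none"`, `"sinusoidal"` or `"checker"` background
#'   texture.
#' @param texture_amp,texture_period Texture amplitude and period (px).
#'   Defaults 0.06 and 9.
#' @param noise_sd Additive Gaussian noise standard deviation. Default 0.
#' @param gaps List of `c(angle_deg, width_deg)` arcs (angle measured from
#'   the +col axis, counter-clockwise with row pointing down) where the
#'   boundary contrast is erased. Default none.
#' @param gap_taper Additional angular taper (degrees) on each side of a
#'   gap over which the contrast fades in. Default 8.
#' @param seed RNG seed making the phantom fully reproducible. Default 1.
#' @return A `phantom_spec` list.
#' @export
phantom_spec <- function(shape = c("disk", "ellipse", "blob"), size = 128,
                         center = NULL, r = 30, axes = c(24, 34), rotation = 0,
                         blob_amp = 0.12,
                         intensity = c("uniform", "ramp", "radial"),
                         object_level = 0.30, background_level = 0.70,
                         texture = c("none", "sinusoidal", "checker"),
                         texture_amp = 0.06, texture_period = 9,
                         noise_sd = 0, gaps = list(), gap_taper = 8,
                         seed = 1) {
  shape <- match.arg(shape)
  intensity <- match.arg(intensity)
  texture <- match.arg(texture)
  check_scalar(size, "size")
  if (is.null(center)) center <- c(size, size) / 2 + 0.5
  if (length(gaps) && !is.list(gaps)) gaps <- list(gaps)
  tot <- sum(vapply(gaps, function(g) g[2], numeric(1)))
  if (tot >= 350) stop_input("gap arcs cover (almost) the entire boundary")
  structure(list(shape = shape, size = as.integer(size), center = center,
                 r = r, axes = axes, rotation = rotation, blob_amp = blob_amp,
                 intensity = intensity, object_level = object_level,
                 background_level = background_level, texture = texture,
                 texture_amp = texture_amp, texture_period = texture_period,
                 noise_sd = noise_sd, gaps = gaps, gap_taper = gap_taper,
                 seed = seed),
            class = "phantom_spec")
}

# radius of the object boundary at polar angle theta (radians)
phantom_radius <- function(spec, theta) {
  switch(spec$shape,
    disk = rep(spec$r, length(theta)),
    ellipse = {
      t2 <- theta - spec$rotation
      a <- spec$axes[2]; b <- spec$axes[1]   # col semi-axis, row semi-axis
      (a * b) / sqrt((b * cos(t2))^2 + (a * sin(t2))^2)
    },
    blob = {
      co <- blob_coefs(spec)
      pert <- rowSums(matrix(vapply(seq_len(5), function(k)
        co$a[k] * cos(k * theta + co$phi[k]), numeric(length(theta))),
        nrow = length(theta)))
      spec$r * (1 + pert)
    })
}

blob_coefs <- function(spec) {
  with_seed(spec$seed * 7L + 13L, {
    a <- runif(5, -1, 1)
    a <- a / max(1, sum(abs(a)) / spec$blob_amp)   # total perturbation bounded
    phi <- runif(5, 0, 2 * pi)
    list(a = a, phi = phi)
  })
}

#' Generate a phantom image with ground truth
#'
#' @param spec A [phantom_spec()].
#' @return List with `image` (matrix in \[0, 1\]), `mask` (logical
#'   ground-truth mask, unaffected by noise and gaps), `boundary` (tibble of
#'   analytic boundary points `row`, `col`, `theta`), and `spec`.
#' @export
gen_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  n <- spec$size
  rr <- matrix(seq_len(n), n, n)
  cc <- matrix(seq_len(n), n, n, byrow = TRUE)
  dr <- rr - spec$center[1]
  dc <- cc - spec$center[2]
  theta <- atan2(dr, dc)
  rad <- sqrt(dr^2 + dc^2)
  rb <- matrix(phantom_radius(spec, as.numeric(theta)), n, n)
  mask <- rad <= rb

  bg <- matrix(spec$background_level, n, n)
  ob <- matrix(spec$object_level, n, n)
  if (spec$intensity == "ramp") {
    bg <- bg + 0.3 * (cc - n / 2) / n     # left-right background ramp
  } else if (spec$intensity == "radial") {
    ob <- ob + 0.20 * pmin(rad / max(rb), 1)  # object brightens outward
  }
  if (spec$texture == "sinusoidal") {
    tex <- spec$texture_amp * sin(2 * pi * rr / spec$texture_period) *
                              sin(2 * pi * cc / spec$texture_period)
    bg <- bg + tex
  } else if (spec$texture == "checker") {
    tex <- spec$texture_amp * (2 * ((floor(rr / spec$texture_period) +
                                     floor(cc / spec$texture_period)) %% 2) - 1)
    bg <- bg + tex
  }
  img <- ifelse(mask, ob, bg)

  # gaps: cross-fade object and background intensities across the boundary
  # inside the arc, erasing the local edge while the truth mask is untouched
  for (g in spec$gaps) {
    ga <- g[1] * pi / 180; gw <- g[2] * pi / 180 / 2
    taper <- spec$gap_taper * pi / 180
    dang <- abs(((theta - ga + pi) %% (2 * pi)) - pi)
    w_ang <- ifelse(dang <= gw, 1,
                    ifelse(dang <= gw + taper,
                           0.5 * (1 + cos(pi * (dang - gw) / taper)), 0))
    mid <- (ob + bg) / 2
    img <- img + w_ang * (mid - img)
  }

  if (spec$noise_sd > 0) img <- gen_noise(img, spec$noise_sd, spec$seed)
  img <- pmin(pmax(img, 0), 1)

  tb <- seq(0, 2 * pi, length.out = 720)
  rbnd <- phantom_radius(spec, tb)
  boundary <- tibble::tibble(row = spec$center[1] + rbnd * sin(tb),
                             col = spec$center[2] + rbnd * cos(tb),
                             theta = tb)
  list(image = img, mask = mask, boundary = boundary, spec = spec)
}

#' Additive Gaussian noise
#'
#' Seeded, clipped to \[0, 1\]; the caller's RNG state is untouched.
#'
#' @param image Numeric matrix in \[0, 1\].
#' @param sigma_n Noise standard deviation (>= 0).
#' @param seed RNG seed.
#' @return Noisy matrix.
#' @export
gen_noise <- function(image, sigma_n, seed = 1) {
  if (sigma_n < 0) stop_param("`sigma_n` must be >= 0")
  if (sigma_n == 0) return(image)
  noise <- with_seed(seed, matrix(rnorm(length(image), 0, sigma_n),
                                  nrow(image), ncol(image)))
  pmin(pmax(image + noise, 0), 1)
}

#' Generate a grooved plate thickness field
#'
#' Builds an `n x n` plate of thickness `H` with a groove of the given
#' depth carved along a straight line, a quarter-circle arc, or a random
#' smooth spline, together with the analytic groove centreline.
#'
#' @param H Plate thickness. Default 10.
#' @param depth Groove depth; groove pixels have thickness `H - depth`.
#'   Must satisfy `1 <= H - depth < H` for a groove to exist (depth 0 gives
#'   a uniform plate).
#' @param path `"straight"`, `"arc"` or `"spline"`.
#' @param n Plate side in elements. Default 31.
#' @param seed Seed for the spline path. Default 1.
#' @return List with `thickness` (a `thickness_field`-like matrix),
#'   `centerline` (two-column matrix of `(row, col)` points in pixel-centre
#'   coordinates), `groove` (pixel index matrix) and `seed_points`
#'   (suggested crack seed node coordinates at the groove start).
#' @export
gen_groove_plate <- function(H = 10, depth = H - 1,
                             path = c("straight", "arc", "spline"),
                             n = 31L, seed = 1) {
  path <- match.arg(path)
  check_scalar(H, "H")
  if (depth < 0 || depth >= H) stop_param("`depth` must satisfy 0 <= depth < H")
  th <- matrix(H, n, n)
  mid <- (n + 1) %/% 2
  if (depth == 0) {
    return(list(thickness = th, centerline = NULL, groove = NULL,
                seed_points = cbind(mid, 2:5)))
  }
  if (path == "straight") {
    th[mid, ] <- H - depth
    centerline <- cbind(rep(mid - 0.5, 4 * n), seq(0, n, length.out = 4 * n))
    seed_pts <- cbind(mid, 2:5)
  } else if (path == "arc") {
    R <- 0.65 * n
    ij <- expand.grid(i = seq_len(n), j = seq_len(n))
    d <- sqrt((ij$i - 0.5)^2 + (ij$j - 0.5)^2)
    sel <- abs(d - R) < 0.6
    th[as.matrix(ij)[sel, ]] <- H - depth
    tt <- seq(0, pi / 2, length.out = 4 * n)
    centerline <- cbind(R * cos(tt), R * sin(tt))
    # seed node rows track the rasterised groove in the first columns
    gr <- vapply(1:4, function(j) {
      cand <- which(th[, j] < H)
      cand[which.min(abs(cand - R))]
    }, integer(1))
    seed_pts <- snap_path(cbind(gr, 1:4))
  } else {
    f <- with_seed(seed, {
      kn <- stats::runif(5, 0.3 * n, 0.7 * n)
      stats::splinefun(seq(1, n, length.out = 5), kn, method = "natural")
    })
    rows <- pmin(pmax(round(f(seq_len(n))), 2), n - 1)
    prev <- rows[1]
    for (j in seq_len(n)) {
      th[min(prev, rows[j]):max(prev, rows[j]), j] <- H - depth
      prev <- rows[j]
    }
    cs <- seq(1, n, by = 0.25)
    centerline <- cbind(f(cs) - 0.5, cs - 0.5)
    seed_pts <- snap_path(cbind(rows[1:4], 1:4))
  }
  groove <- which(th < H, arr.ind = TRUE)
  list(thickness = structure(th, H = H, degenerate = FALSE,
                             class = c("thickness_field", "matrix", "array")),
       centerline = centerline, groove = groove, seed_points = seed_pts)
}

#' First-window centre and manual seed from a phantom's analytic boundary
#'
#' Convenience for tests and benchmarks: places the first local window on
#' the true boundary at polar angle `angle` and returns a short tangential
#' seed there, mimicking the manual seeding a user would do on a clear
#' stretch of boundary.
#'
#' @param phantom A [gen_phantom()] result.
#' @param angle Polar angle (radians, from the +col axis). Default `pi`
#'   (left side, far from the default gap position).
#' @param len Seed length in pixels. Default 4.
#' @return List with `center` (row, col) and `seed` (2 x 2 matrix of global
#'   seed endpoints).
#' @export
phantom_seed <- function(phantom, angle = pi, len = 4) {
  spec <- phantom$spec
  r0 <- phantom_radius(spec, angle)
  p <- spec$center + r0 * c(sin(angle), cos(angle))
  tang <- unitv(c(cos(angle), -sin(angle)))
  list(center = round(p),
       seed = rbind(p - len / 2 * tang, p + len / 2 * tang))
}

#' Phantom presets matching the synthetic test regimes
#'
#' `"inhomog_bg"`: blob with a linear background ramp; `"inhomog_obj"`:
#' ellipse with a radially inhomogeneous object; `"textured"`: disk on a
#' sinusoidal background; `"textured_noise"`: blob with texture plus noise;
#' `"inhomog_noise"`: ellipse with a background ramp plus Gaussian noise;
#' `"gapped"`: disk with an invisible boundary arc.
#'
#' @param name Preset name.
#' @param seed RNG seed for the phantom.
#' @param size Image side; default 128.
#' @return A [phantom_spec()].
#' @export
phantom_preset <- function(name = c("inhomog_bg", "inhomog_obj", "textured",
                                    "textured_noise", "inhomog_noise", "gapped"),
                           seed = 1, size = 128) {
  name <- match.arg(name)
  switch(name,
    inhomog_bg = phantom_spec("blob", size = size, r = 28, intensity = "ramp",
                              seed = seed),
    inhomog_obj = phantom_spec("ellipse", size = size, axes = c(24, 32),
                               rotation = 0.4, intensity = "radial", seed = seed),
    textured = phantom_spec("disk", size = size, r = 30, texture = "sinusoidal",
                            seed = seed),
    textured_noise = phantom_spec("blob", size = size, r = 27,
                                  texture = "sinusoidal", noise_sd = 0.03,
                                  seed = seed),
    inhomog_noise = phantom_spec("ellipse", size = size, axes = c(28, 22),
                                 rotation = -0.3, intensity = "ramp",
                                 noise_sd = 0.04, seed = seed),
    gapped = phantom_spec("disk", size = size, r = 30,
                          gaps = list(c(0, 10)), seed = seed))
}
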