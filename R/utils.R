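# Internal helpers: argument checking, conditions, seeded RNG.

stop_input <- function(msg, class = "crackseg_input_error") {
  rlang::abort(msg, class = c(class, "crackseg_error"))
}

stop_param <- function(msg) {
  rlang::abort(msg, class = c("crackseg_parameter_error", "crackseg_error"))
}

stop_solver <- function(msg) {
  rlang::abort(msg, class = c("crackseg_solver_error", "crackseg_error"))
}

check_scalar <- function(x, name, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_param(sprintf("`%s` must be a single finite number", name))
  if (positive && x <= 0)
    stop_param(sprintf("`%s` must be > 0 (got %g)", name, x))
  invisible(x)
}

check_image <- function(x, name = "image", min_dim = 3L) {
  if (!is.matrix(x) || !is.numeric(x))
    stop_input(sprintf("`%s` must be a numeric matrix", name))
  if (nrow(x) < min_dim || ncol(x) < min_dim)
    stop_input(sprintf("`%s` must be at least %dx%d", name, min_dim, min_dim))
  invisible(x)
}

# Evaluate `expr` under a fixed RNG state without disturbing the caller's stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# unit vector; zero-safe
unitv <- function(v) {
  n <- sqrt(sum(v^2))
  if (n == 0) return(c(0, 0))
  v / n
}

vnorm <- function(v) sqrt(sum(v^2))

# distance from each row of `pts` (n x 2) to the nearest row of `ref` (m x 2)
nearest_dist <- function(pts, ref) {
  pts <- rbind(pts); ref <- rbind(ref)
  d2 <- outer(pts[, 1], ref[, 1], "-")^2 + outer(pts[, 2], ref[, 2], "-")^2
  sqrt(apply(d2, 1, min))
}
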