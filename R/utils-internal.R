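# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
vnorm <- function(v) sqrt(sum(v * v))

#' @noRd
unit <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero vector")
  v / n
}

#' @noRd
cross3 <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

# Squared distances from one point to each row of a matrix.
#' @noRd
dist2_to_point <- function(m, p) {
  (m[, 1L] - p[1L])^2 + (m[, 2L] - p[2L])^2 + (m[, 3L] - p[3L])^2
}

# Minimum distance between two coordinate sets; computed blockwise so the
# full cross matrix never exceeds ~1e7 entries.
#' @noRd
min_cross_dist <- function(a, b) {
  na <- nrow(a)
  block <- max(1L, floor(1e7 / max(1L, nrow(b))))
  best <- Inf
  i <- 1L
  while (i <= na) {
    j <- min(na, i + block - 1L)
    d2 <- outer(rowSums(a[i:j, , drop = FALSE]^2), rowSums(b^2), "+") -
      2 * (a[i:j, , drop = FALSE] %*% t(b))
    best <- min(best, min(d2))
    i <- j + 1L
  }
  sqrt(max(best, 0))
}

# Full cross-distance matrix (small inputs only).
#' @noRd
cross_dist <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * (a %*% t(b))
  sqrt(pmax(d2, 0))
}

# Run expr with a private RNG stream, restoring the caller's .Random.seed.
#' @noRd
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(as.integer(seed))
  force(expr)
}

# Lower median: order statistic ceiling(n/2); deterministic for even n.
#' @noRd
lower_median <- function(x) {
  x <- sort(x)
  x[ceiling(length(x) / 2)]
}

# Quaternion utilities (unit quaternions, scalar-first convention).

#' @noRd
quat_random <- function(n) {
  q <- matrix(stats::rnorm(4L * n), ncol = 4L)
  q / sqrt(rowSums(q^2))
}

#' @noRd
quat_to_rot <- function(q) {
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3L, byrow = TRUE)
}

#' @noRd
rot_to_quat <- function(R) {
  tr <- R[1L, 1L] + R[2L, 2L] + R[3L, 3L]
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3L, 2L] - R[2L, 3L]) / s,
           (R[1L, 3L] - R[3L, 1L]) / s, (R[2L, 1L] - R[1L, 2L]) / s)
  } else {
    i <- which.max(c(R[1L, 1L], R[2L, 2L], R[3L, 3L]))
    if (i == 1L) {
      s <- sqrt(1 + R[1L, 1L] - R[2L, 2L] - R[3L, 3L]) * 2
      q <- c((R[3L, 2L] - R[2L, 3L]) / s, 0.25 * s,
             (R[1L, 2L] + R[2L, 1L]) / s, (R[1L, 3L] + R[3L, 1L]) / s)
    } else if (i == 2L) {
      s <- sqrt(1 + R[2L, 2L] - R[1L, 1L] - R[3L, 3L]) * 2
      q <- c((R[1L, 3L] - R[3L, 1L]) / s, (R[1L, 2L] + R[2L, 1L]) / s,
             0.25 * s, (R[2L, 3L] + R[3L, 2L]) / s)
    } else {
      s <- sqrt(1 + R[3L, 3L] - R[1L, 1L] - R[2L, 2L]) * 2
      q <- c((R[2L, 1L] - R[1L, 2L]) / s, (R[1L, 3L] + R[3L, 1L]) / s,
             (R[2L, 3L] + R[3L, 2L]) / s, 0.25 * s)
    }
  }
  q / vnorm(q)
}

# Gas constant in kJ/mol/K.
GAS_CONSTANT <- 0.008314462618
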