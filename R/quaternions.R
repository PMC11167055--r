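# Quaternion algebra on row matrices, Hamilton convention (w, x, y, z).
# All routines are vectorized over rows so a whole kinematic log is
# transformed without per-frame loops.

quatNormalizeRows <- function(q) {
  n <- sqrt(rowSums(q^2))
  if (any(n == 0)) stop("zero-norm quaternion", call. = FALSE)
  q / n
}

quatConjugateRows <- function(q) {
  cbind(q[, 1L], -q[, 2L], -q[, 3L], -q[, 4L], deparse.level = 0)
}

# Hamilton product a %*% b, rowwise
quatMultiplyRows <- function(a, b) {
  aw <- a[, 1L]; ax <- a[, 2L]; ay <- a[, 3L]; az <- a[, 4L]
  bw <- b[, 1L]; bx <- b[, 2L]; by <- b[, 3L]; bz <- b[, 4L]
  cbind(
    aw * bw - ax * bx - ay * by - az * bz,
    aw * bx + ax * bw + ay * bz - az * by,
    aw * by - ax * bz + ay * bw + az * bx,
    aw * bz + ax * by - ay * bx + az * bw,
    deparse.level = 0)
}

# Rotate row vectors v (n x 3) by unit quaternions q (n x 4):
# v' = v + 2 q_v x (q_v x v + w v)
quatRotateRows <- function(q, v) {
  w <- q[, 1L]
  qv <- q[, 2:4, drop = FALSE]
  crossRows <- function(a, b) {
    cbind(a[, 2L] * b[, 3L] - a[, 3L] * b[, 2L],
          a[, 3L] * b[, 1L] - a[, 1L] * b[, 3L],
          a[, 1L] * b[, 2L] - a[, 2L] * b[, 1L],
          deparse.level = 0)
  }
  t1 <- crossRows(qv, v) + v * w
  v + 2 * crossRows(qv, t1)
}

# random unit quaternion rows (uniform-ish via normalized gaussians)
randomUnitQuatRows <- function(n) {
  quatNormalizeRows(matrix(stats::rnorm(n * 4L), n, 4L))
}
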