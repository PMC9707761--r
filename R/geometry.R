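# Internal vectorized 3-D geometry.  All helpers operate row-wise on
# n x 3 matrices so that tensor cost functions can score whole candidate
# batches at once.

.as_row3 <- function(v) {
  if (is.matrix(v)) return(v)
  matrix(as.numeric(v), nrow = 1L, ncol = 3L)
}

.row_dot <- function(a, b) rowSums(a * b)

.row_norm <- function(a) sqrt(rowSums(a * a))

.row_cross <- function(a, b) {
  cbind(a[, 2] * b[, 3] - a[, 3] * b[, 2],
        a[, 3] * b[, 1] - a[, 1] * b[, 3],
        a[, 1] * b[, 2] - a[, 2] * b[, 1])
}

.row_unit <- function(a, what = "vector") {
  n <- .row_norm(a)
  if (any(n <= 0 | !is.finite(n))) stop("degenerate ", what, " (zero length)")
  a / n
}

# Unsigned angle between row vectors, degrees in [0, 180].  atan2 form is
# numerically stable near 0 and 180.
.row_angle <- function(u, v) {
  atan2(.row_norm(.row_cross(u, v)), .row_dot(u, v)) * 180 / pi
}

# Signed dihedral angle (degrees, (-180, 180]) between rows of a and b
# about the (row) axis c: positive when b is rotated counterclockwise from
# a looking down c.
.row_dihedral <- function(a, b, axis) {
  ax <- .row_unit(axis, "axis chord")
  u <- a - .row_dot(a, ax) * ax
  v <- b - .row_dot(b, ax) * ax
  if (any(.row_norm(u) <= 1e-12 * .row_norm(a)) ||
      any(.row_norm(v) <= 1e-12 * .row_norm(b)))
    stop("degenerate dihedral: a pair axis is parallel to the midpoint chord")
  ang <- atan2(.row_dot(.row_cross(u, v), ax), .row_dot(u, v)) * 180 / pi
  ifelse(ang <= -180, ang + 360, ang)
}

# Total-least-squares plane normal for a small point cloud (rows of P).
# Errors when the points are (numerically) collinear.
.plane_normal <- function(P) {
  C <- sweep(P, 2L, colMeans(P))
  e <- eigen(crossprod(C), symmetric = TRUE)
  if (e$values[2] <= 1e-10 * max(e$values[1], .Machine$double.eps))
    stop("rank-deficient point set: no well-defined best-fit plane")
  e$vectors[, 3L]
}
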