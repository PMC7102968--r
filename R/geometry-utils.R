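# Small 3-D geometry helpers shared across modules.  All angles are in
# degrees on the interval (-180, 180] unless stated otherwise.

vec_norm <- function(v) sqrt(sum(v * v))

unit_vec <- function(v) {
  n <- vec_norm(v)
  if (n < .Machine$double.eps) stop("cannot normalize a zero-length vector")
  v / n
}

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

deg <- function(x) x * 180 / pi
rad <- function(x) x * pi / 180

#' Signed dihedral angle of four points
#'
#' Returns the torsion angle p1-p2-p3-p4 using the standard sign
#' convention (positive = clockwise rotation of p4 relative to p1 when
#' looking from p2 towards p3), in degrees in (-180, 180].
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstroms).
#' @return Angle in degrees.
#' @export
dihedral_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m1 <- cross3(n1, unit_vec(b2))
  x <- sum(n1 * n2)
  y <- sum(m1 * n2)
  ang <- deg(atan2(y, x))
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Rotation matrix about an arbitrary axis
#'
#' @param axis Direction 3-vector (normalized internally).
#' @param angle_deg Rotation angle, degrees.
#' @return 3x3 proper rotation matrix.
#' @export
rotation_about_axis <- function(axis, angle_deg) {
  a <- unit_vec(axis)
  th <- rad(angle_deg)
  ct <- cos(th); st <- sin(th)
  K <- matrix(c(0, -a[3], a[2],
                a[3], 0, -a[1],
                -a[2], a[1], 0), 3, 3, byrow = TRUE)
  diag(3) * ct + st * K + (1 - ct) * (a %o% a)
}

# Axis-angle decomposition of a proper rotation matrix, robust near 180
# degrees (where the skew-symmetric part vanishes).
rotation_axis_angle <- function(R) {
  tr <- sum(diag(R))
  ct <- max(-1, min(1, (tr - 1) / 2))
  angle <- deg(acos(ct))
  if (angle < 1e-7) return(list(axis = c(0, 0, 1), angle = 0))
  if (angle > 179.999) {
    # eigenvector for eigenvalue +1 of R (real symmetric part works too)
    ev <- eigen(R)
    i <- which.min(abs(ev$values - 1))
    axis <- Re(ev$vectors[, i])
    axis <- unit_vec(axis)
    # sign is arbitrary at exactly 180 deg; fix a convention
    s <- c(axis[3], axis[2], axis[1])
    nz <- which(abs(axis) > 1e-8)[1]
    if (axis[nz] < 0) axis <- -axis
    return(list(axis = axis, angle = angle))
  }
  v <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  list(axis = unit_vec(v), angle = angle)
}

# Apply rigid transform x -> x R^T + t to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, R, t) {
  sweep(xyz %*% t(R), 2, -t)
}

# All pairwise Euclidean distances between rows of two n x 3 matrices.
cross_distances <- function(a, b) {
  a2 <- rowSums(a * a)
  b2 <- rowSums(b * b)
  d2 <- outer(a2, b2, "+") - 2 * (a %*% t(b))
  d2[d2 < 0] <- 0
  sqrt(d2)
}

# Best-fit plane through n x 3 points: centroid + unit normal (smallest
# principal direction).
plane_fit <- function(xyz) {
  ctr <- colMeans(xyz)
  x <- sweep(xyz, 2, ctr)
  s <- svd(x, nu = 0, nv = 3)
  list(centroid = ctr, normal = s$v[, 3])
}

# Acute angle (degrees, in [0, 90]) between two directions.
acute_angle <- function(u, v) {
  cu <- abs(sum(unit_vec(u) * unit_vec(v)))
  deg(acos(max(-1, min(1, cu))))
}
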