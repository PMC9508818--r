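# Low-level vector geometry shared by every measurement in the package.
# All angles are degrees unless a name says otherwise; coordinates are Angstrom.

DEG <- pi / 180

vnorm <- function(v) sqrt(sum(v^2))

unitize <- function(v) {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalize a zero-length vector", call. = FALSE)
  v / n
}

cross3 <- function(a, b) {
  c(
    a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1]
  )
}

#' Signed dihedral angle between four points
#'
#' Computes the torsion angle about the p2--p3 bond using the
#' `atan2((n1 x n2) . b2hat, n1 . n2)` construction, which is free of the
#' quadrant ambiguity of acos-based forms. The sign follows the IUPAC
#' convention: looking from `p2` toward `p3`, a clockwise rotation of the
#' far bond relative to the near bond is positive.
#'
#' @param p1,p2,p3,p4 Numeric 3-vectors (Angstrom).
#' @return Angle in degrees in the interval (-180, 180].
#' @examples
#' dihedral(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(1, 1, 1)) # +90
#' @export
dihedral <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  if (vnorm(b1) < 1e-9 || vnorm(b2) < 1e-9 || vnorm(b3) < 1e-9) {
    stop("degenerate geometry: two consecutive points coincide", call. = FALSE)
  }
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  if (vnorm(n1) < 1e-9 || vnorm(n2) < 1e-9) {
    stop("degenerate geometry: collinear bonded triple", call. = FALSE)
  }
  b2h <- unitize(b2)
  ang <- atan2(sum(cross3(n1, n2) * b2h), sum(n1 * n2)) / DEG
  wrap_angle(ang)
}

#' Bond angle at p2 (degrees)
#' @param p1,p2,p3 Numeric 3-vectors.
#' @return Angle in degrees in [0, 180].
#' @export
bond_angle <- function(p1, p2, p3) {
  u <- unitize(p1 - p2)
  v <- unitize(p3 - p2)
  acos(max(-1, min(1, sum(u * v)))) / DEG
}

#' Wrap an angle into (-180, 180]
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle <- function(x) {
  y <- (x + 180) %% 360 - 180
  ifelse(abs(y + 180) < 1e-12, 180, y)
}

#' Wrap an angle into [0, 360)
#' @param x Angle(s) in degrees.
#' @return Wrapped angle(s).
#' @export
wrap_angle_360 <- function(x) x %% 360

#' Shortest signed angular difference a - b in (-180, 180]
#' @param a,b Angles in degrees.
#' @return Signed difference in degrees.
#' @export
angle_diff <- function(a, b) wrap_angle(a - b)

# Rotation matrix about an arbitrary unit axis (Rodrigues), angle in degrees.
rotation_about <- function(axis, angle_deg) {
  u <- unitize(axis)
  th <- angle_deg * DEG
  K <- matrix(
    c(0, -u[3], u[2], u[3], 0, -u[1], -u[2], u[1], 0),
    nrow = 3, byrow = TRUE
  )
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

# Random proper rotation, uniform over SO(3) (quaternion method).
random_rotation <- function() {
  q <- stats::rnorm(4)
  q <- q / vnorm(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

# Convert a rotation matrix to (axis, angle in degrees). The antisymmetric
# part gives the axis except near 0 and 180 degrees, where it vanishes;
# those cases fall back to identity / the symmetric-part projector.
rotation_axis_angle <- function(R) {
  ang <- acos(max(-1, min(1, (sum(diag(R)) - 1) / 2))) / DEG
  ax <- c(R[3, 2] - R[2, 3], R[1, 3] - R[3, 1], R[2, 1] - R[1, 2])
  if (vnorm(ax) < 1e-10) {
    if (ang < 90) {
      return(list(axis = c(0, 0, 1), angle = 0))
    }
    # 180-degree rotation: axis from the largest diagonal of (R + I)/2
    B <- (R + diag(3)) / 2
    i <- which.max(diag(B))
    return(list(axis = unitize(B[, i] / sqrt(B[i, i])), angle = 180))
  }
  list(axis = unitize(ax), angle = ang)
}

# Apply a rigid transform to an n x 3 coordinate matrix.
apply_rigid <- function(xyz, R, t = c(0, 0, 0)) {
  sweep(as.matrix(xyz) %*% t(R), 2, -t)
}

# Apply a rigid transform to the coord columns of an atom tibble.
transform_atoms <- function(atoms, R, t = c(0, 0, 0)) {
  xyz <- apply_rigid(as.matrix(atoms[, c("x", "y", "z")]), R, t)
  atoms$x <- xyz[, 1]
  atoms$y <- xyz[, 2]
  atoms$z <- xyz[, 3]
  atoms
}

# Half-rotation interpolation: the proper rotation "halfway" between I and R.
half_rotation <- function(R) {
  aa <- rotation_axis_angle(R)
  rotation_about(aa$axis, aa$angle / 2)
}

# Place atom D given bonded atoms C (bond partner), B, A defining the
# internal coordinates: |CD| = len, angle(B,C,D) = ang, dihedral(A,B,C,D) = tor.
place_atom <- function(A, B, C, len, ang, tor) {
  bc <- unitize(C - B)
  n <- unitize(cross3(B - A, bc))
  m <- cross3(n, bc)
  th <- (180 - ang) * DEG
  ph <- tor * DEG
  d_local <- c(
    len * cos(th),
    len * sin(th) * cos(ph),
    len * sin(th) * sin(ph)
  )
  C + d_local[1] * bc + d_local[2] * m + d_local[3] * n
}
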