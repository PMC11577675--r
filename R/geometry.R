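# Small 3D geometry toolkit used throughout the package.
#
# Every point is a plain numeric length-3 vector in millimetres, expressed in
# the package's single coordinate convention: right-handed, +X lateral (for a
# right limb), +Y anterior, +Z proximal. Left limbs are mirrored into this
# convention at creation time.

#' Euclidean norm of a 3-vector
#' @param v numeric(3)
#' @return scalar length
#' @keywords internal
vnorm <- function(v) sqrt(sum(v * v))

#' Normalise a 3-vector to unit length
#' @param v numeric(3)
#' @return unit vector
#' @keywords internal
unitv <- function(v) {
  n <- vnorm(v)
  if (!is.finite(n) || n < 1e-12) stop("cannot normalise a (near-)zero vector")
  v / n
}

#' Cross product of two 3-vectors
#' @param a,b numeric(3)
#' @keywords internal
vcross <- function(a, b) {
  c(a[2L] * b[3L] - a[3L] * b[2L],
    a[3L] * b[1L] - a[1L] * b[3L],
    a[1L] * b[2L] - a[2L] * b[1L])
}

deg2rad <- function(x) x * pi / 180
rad2deg <- function(x) x * 180 / pi

#' Rotation matrix about an arbitrary axis (Rodrigues form)
#'
#' @param axis direction of the rotation axis; normalised internally.
#' @param angle_rad rotation angle in radians (right-hand rule).
#' @return 3x3 rotation matrix
#' @keywords internal
rotation_about_axis <- function(axis, angle_rad) {
  a <- unitv(axis)
  c_ <- cos(angle_rad)
  s_ <- sin(angle_rad)
  K <- matrix(c(0, a[3L], -a[2L],
                -a[3L], 0, a[1L],
                a[2L], -a[1L], 0), 3L, 3L)
  diag(3L) * c_ + s_ * K + (1 - c_) * tcrossprod(a)
}

#' Rigid transform: rotation R about a fixed point
#'
#' Stored as a list with elements `R` (3x3) and `t` (numeric(3)) so that a
#' point maps as `R %*% p + t`.
#'
#' @param R 3x3 rotation matrix
#' @param point fixed point of the rotation
#' @return an object of class `hto_rigid`
#' @keywords internal
rigid_about_point <- function(R, point) {
  structure(list(R = R, t = as.numeric(point - R %*% point)),
            class = "hto_rigid")
}

#' Identity rigid transform
#' @keywords internal
rigid_identity <- function() {
  structure(list(R = diag(3L), t = c(0, 0, 0)), class = "hto_rigid")
}

#' Apply a rigid transform to one point or a matrix of points
#'
#' @param tf `hto_rigid`
#' @param p numeric(3) or an N x 3 matrix of row points
#' @return transformed point(s), same shape as input
#' @keywords internal
apply_rigid <- function(tf, p) {
  if (is.matrix(p)) {
    sweep(p %*% t(tf$R), 2L, tf$t, "+")
  } else {
    as.numeric(tf$R %*% p + tf$t)
  }
}

#' Check that a matrix is a proper rotation
#' @param R 3x3 matrix
#' @param tol orthonormality tolerance
#' @keywords internal
is_proper_rotation <- function(R, tol = 1e-9) {
  max(abs(crossprod(R) - diag(3L))) < tol && abs(det(R) - 1) < tol
}

#' Signed distance of points to a plane
#' @param p numeric(3) or N x 3 matrix
#' @param point a point on the plane
#' @param normal plane normal (normalised internally)
#' @keywords internal
plane_signed_distance <- function(p, point, normal) {
  n <- unitv(normal)
  if (is.matrix(p)) {
    as.numeric(sweep(p, 2L, point, "-") %*% n)
  } else {
    sum((p - point) * n)
  }
}

#' Perpendicular distance from a point to a line
#' @param p query point
#' @param line_point point on the line
#' @param line_dir direction of the line
#' @keywords internal
point_line_distance <- function(p, line_point, line_dir) {
  d <- unitv(line_dir)
  v <- p - line_point
  vnorm(v - sum(v * d) * d)
}

#' Mirror points in the sagittal (x = 0) plane
#' @param p numeric(3) or N x 3 matrix
#' @keywords internal
mirror_x <- function(p) {
  if (is.matrix(p)) {
    p[, 1L] <- -p[, 1L]
    p
  } else {
    c(-p[1L], p[2L], p[3L])
  }
}

#' Angle between two vectors in degrees
#' @keywords internal
vangle_deg <- function(a, b) {
  ca <- sum(unitv(a) * unitv(b))
  rad2deg(acos(max(-1, min(1, ca))))
}

#' Orthonormalise `v` against unit vector `u`
#' @keywords internal
orthogonalise <- function(v, u) unitv(v - sum(v * u) * u)
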