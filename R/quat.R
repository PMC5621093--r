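# Quaternion algebra for sensor-to-world rotation tracking.
#
# Quaternions are plain numeric length-4 vectors, scalar-first (q0, q1, q2, q3),
# Hamilton convention. Throughout the package a quaternion maps sensor-frame
# vectors into the world frame whose -y axis is gravity.

#' Build a quaternion from an axis and an angle
#'
#' @param axis Numeric length-3 rotation axis (need not be unit length).
#' @param angle Rotation angle in radians.
#' @return Numeric length-4 unit quaternion, scalar first.
#' @examples
#' quat_from_axis_angle(c(0, 0, 1), pi / 2)
#' @export
quat_from_axis_angle <- function(axis, angle) {
  nrm <- sqrt(sum(axis^2))
  if (nrm == 0) stop("rotation axis must be non-zero")
  u <- axis / nrm
  c(cos(angle / 2), sin(angle / 2) * u)
}

#' Identity quaternion
#' @return The quaternion (1, 0, 0, 0).
#' @export
quat_identity <- function() c(1, 0, 0, 0)

#' Hamilton product of two quaternions
#'
#' Composition of rotations: `quat_multiply(a, b)` rotates first by `b`,
#' then by `a` (matrix product R(a) R(b)).
#'
#' @param a,b Numeric length-4 quaternions, scalar first.
#' @return Their Hamilton product a %*% b as a length-4 numeric vector.
#' @export
quat_multiply <- function(a, b) {
  c(
    a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1]
  )
}

#' Quaternion conjugate
#' @param q Numeric length-4 quaternion.
#' @return The conjugate (q0, -q1, -q2, -q3); the inverse rotation for unit q.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalise a quaternion to unit length
#'
#' A drift guard warns when the pre-normalisation norm deviates from 1 by
#' more than `guard`; per-sample filter updates should never drift that far.
#'
#' @param q Numeric length-4 quaternion.
#' @param guard Tolerated norm deviation before a warning is raised.
#' @return Unit quaternion.
#' @export
quat_normalize <- function(q, guard = NULL) {
  nrm <- sqrt(sum(q^2))
  if (nrm == 0) stop("cannot normalise a zero quaternion")
  if (!is.null(guard) && abs(nrm - 1) > guard) {
    warning(sprintf("quaternion norm drifted to %.8f before renormalisation", nrm))
  }
  q / nrm
}

#' Rotation matrix of a unit quaternion
#'
#' Returns the 3x3 matrix R(q) mapping sensor-frame vectors to the world
#' frame; its transpose maps world to sensor.
#'
#' @param q Unit quaternion (norm within 1e-6 of 1, otherwise an error).
#' @return 3x3 orthonormal rotation matrix with determinant +1.
#' @export
quat_to_matrix <- function(q) {
  nrm <- sqrt(sum(q^2))
  if (abs(nrm - 1) > 1e-6) {
    stop(sprintf("quat_to_matrix() requires a unit quaternion (norm %.8f)", nrm))
  }
  q0 <- q[1]; q1 <- q[2]; q2 <- q[3]; q3 <- q[4]
  matrix(c(
    1 - 2 * (q2^2 + q3^2), 2 * (q1 * q2 - q0 * q3), 2 * (q1 * q3 + q0 * q2),
    2 * (q1 * q2 + q0 * q3), 1 - 2 * (q1^2 + q3^2), 2 * (q2 * q3 - q0 * q1),
    2 * (q1 * q3 - q0 * q2), 2 * (q2 * q3 + q0 * q1), 1 - 2 * (q1^2 + q2^2)
  ), nrow = 3, byrow = TRUE)
}

#' Rotate a 3-vector by a unit quaternion
#' @param q Unit quaternion (sensor-to-world).
#' @param v Numeric length-3 vector in the sensor frame.
#' @return The rotated vector in the world frame.
#' @export
quat_rotate <- function(q, v) {
  as.numeric(quat_to_matrix(q) %*% v)
}

#' Time derivative of a quaternion under a body angular rate
#'
#' First-order strapdown kinematics: `0.5 * q_prev (x) (0, omega)`.
#'
#' @param q_prev Unit quaternion at the previous sample.
#' @param omega Angular rate in rad/s, sensor frame, length 3.
#' @return Length-4 quaternion rate (not unit norm).
#' @export
quat_derivative <- function(q_prev, omega) {
  0.5 * quat_multiply(q_prev, c(0, omega))
}

#' Angle between two rotations
#'
#' Geodesic distance on SO(3) between the rotations represented by `a` and
#' `b`, insensitive to the q / -q sign ambiguity.
#'
#' @param a,b Unit quaternions.
#' @return Angle in radians in `[0, pi]`.
#' @export
quat_angle <- function(a, b = quat_identity()) {
  d <- quat_multiply(quat_conjugate(a), b)
  2 * atan2(sqrt(sum(d[2:4]^2)), abs(d[1]))
}

# Canonical representative (q0 >= 0) used only when comparing quaternions.
quat_canonical <- function(q) if (q[1] < 0) -q else q
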