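#' Quaternion algebra and Euler-angle conversions
#'
#' Orientations are represented as unit quaternions `c(w, x, y, z)` (scalar
#' first). The Earth frame is z-up: a unit at rest in the identity
#' orientation reads an accelerometer vector of (0, 0, 1) g. Euler angles use
#' the intrinsic Z-Y'-X'' (aerospace yaw-pitch-roll) sequence with pitch
#' about the mediolateral y axis, so "pitch" is the sagittal-plane rotation.
#'
#' @name quaternion
NULL

DEG2RAD <- pi / 180
RAD2DEG <- 180 / pi

#' Quaternion product
#'
#' Hamilton product `a` times `b`, both scalar-first 4-vectors.
#'
#' @param a,b numeric quaternions `c(w, x, y, z)`.
#' @return the product quaternion as a numeric 4-vector.
#' @export
#' @examples
#' quat_multiply(c(1, 0, 0, 0), c(0, 1, 0, 0))
quat_multiply <- function(a, b) {
  c(a[1] * b[1] - a[2] * b[2] - a[3] * b[3] - a[4] * b[4],
    a[1] * b[2] + a[2] * b[1] + a[3] * b[4] - a[4] * b[3],
    a[1] * b[3] - a[2] * b[4] + a[3] * b[1] + a[4] * b[2],
    a[1] * b[4] + a[2] * b[3] - a[3] * b[2] + a[4] * b[1])
}

#' Quaternion conjugate
#' @param q numeric quaternion `c(w, x, y, z)`.
#' @return the conjugate quaternion.
#' @export
quat_conjugate <- function(q) c(q[1], -q[2], -q[3], -q[4])

#' Normalize a quaternion to unit norm
#' @param q numeric quaternion.
#' @return unit-norm quaternion.
#' @export
quat_normalize <- function(q) {
  n <- sqrt(sum(q * q))
  if (n == 0) stop("cannot normalize a zero quaternion")
  q / n
}

#' Rotate a 3-vector by a quaternion
#'
#' Applies the rotation that `q` encodes (sensor-to-Earth) to `v`.
#'
#' @param q unit quaternion.
#' @param v numeric 3-vector.
#' @return rotated 3-vector.
#' @export
quat_rotate <- function(q, v) {
  qv <- quat_multiply(quat_multiply(q, c(0, v)), quat_conjugate(q))
  qv[2:4]
}

#' Axis-angle quaternion
#' @param axis numeric 3-vector (need not be unit length).
#' @param angle_deg rotation angle in degrees.
#' @return unit quaternion encoding the rotation.
#' @export
quat_from_axis_angle <- function(axis, angle_deg) {
  axis <- axis / sqrt(sum(axis^2))
  half <- angle_deg * DEG2RAD / 2
  c(cos(half), sin(half) * axis)
}

#' Convert a unit quaternion to yaw-pitch-roll Euler angles
#'
#' Decomposes the rotation in the intrinsic Z-Y'-X'' sequence. At gimbal
#' lock (|pitch| = 90 deg) roll is set to 0 and yaw absorbs the free
#' rotation about the vertical.
#'
#' @param q unit quaternion `c(w, x, y, z)`, or an n-by-4 matrix of them.
#' @param tol maximum allowed deviation of the norm from 1 (default 1e-3).
#' @return named numeric vector `c(yaw, pitch, roll)` in degrees, or a
#'   3-column matrix when `q` is a matrix. Pitch lies in \[-90, 90\] deg,
#'   yaw and roll in (-180, 180\].
#' @export
#' @examples
#' quaternion_to_euler(quat_from_axis_angle(c(0, 1, 0), 30))
quaternion_to_euler <- function(q, tol = 1e-3) {
  if (is.matrix(q)) {
    out <- t(apply(q, 1, quaternion_to_euler, tol = tol))
    colnames(out) <- c("yaw", "pitch", "roll")
    return(out)
  }
  stopifnot(length(q) == 4)
  if (any(!is.finite(q))) stop("non-finite quaternion")
  if (abs(sqrt(sum(q * q)) - 1) > tol) {
    stop("quaternion norm deviates from 1 by more than ", tol)
  }
  q <- quat_normalize(q)
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  sp <- 2 * (w * y - z * x)
  if (abs(sp) >= 1 - 1e-12) {
    # gimbal lock: roll forced to 0, yaw takes the remaining rotation
    pitch <- 90 * sign(sp)
    yaw <- 2 * atan2(z, w) * sign(sp) * RAD2DEG
    yaw <- wrap_deg(yaw)
    return(c(yaw = yaw, pitch = pitch, roll = 0))
  }
  pitch <- asin(sp) * RAD2DEG
  roll <- atan2(2 * (w * x + y * z), 1 - 2 * (x^2 + y^2)) * RAD2DEG
  yaw <- atan2(2 * (w * z + x * y), 1 - 2 * (y^2 + z^2)) * RAD2DEG
  c(yaw = wrap_deg(yaw), pitch = pitch, roll = wrap_deg(roll))
}

#' Build a quaternion from yaw-pitch-roll Euler angles
#'
#' Inverse of [quaternion_to_euler()] away from gimbal lock; same intrinsic
#' Z-Y'-X'' convention.
#'
#' @param yaw,pitch,roll angles in degrees.
#' @return unit quaternion `c(w, x, y, z)`.
#' @export
euler_to_quaternion <- function(yaw = 0, pitch = 0, roll = 0) {
  qz <- quat_from_axis_angle(c(0, 0, 1), yaw)
  qy <- quat_from_axis_angle(c(0, 1, 0), pitch)
  qx <- quat_from_axis_angle(c(1, 0, 0), roll)
  quat_normalize(quat_multiply(quat_multiply(qz, qy), qx))
}

# wrap an angle in degrees to (-180, 180]
wrap_deg <- function(a) {
  a <- (a + 180) %% 360 - 180
  ifelse(a == -180, 180, a)
}

# tilt-only quaternion (yaw = 0) from a measured gravity direction in g;
# identity orientation reads (0, 0, 1)
tilt_from_accel <- function(accel) {
  n <- sqrt(sum(accel^2))
  if (n == 0) return(c(1, 0, 0, 0))
  a <- accel / n
  pitch <- atan2(-a[1], sqrt(a[2]^2 + a[3]^2)) * RAD2DEG
  roll <- atan2(a[2], a[3]) * RAD2DEG
  euler_to_quaternion(yaw = 0, pitch = pitch, roll = roll)
}
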