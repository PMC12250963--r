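#' Madgwick gradient-descent orientation filter (IMU variant)
#'
#' Estimates sensor orientation from a 6-DoF IMU by combining gyroscope
#' integration with a gradient-descent correction that pulls the predicted
#' gravity direction toward the normalized accelerometer reading. The
#' magnetometer-free variant is used throughout: the device this pipeline
#' targets deliberately omits a magnetometer to avoid electromagnetic
#' interference, so yaw is observable only through gyro integration.
#'
#' @name fusion
NULL

#' Fusion settings
#'
#' @param beta filter gain (dimensionless, >= 0). Trades gyro trust against
#'   accelerometer trust; 0 reduces the filter to pure gyro integration.
#'   Default 0.1, in the optimum region reported for IMU-only operation of
#'   the original algorithm.
#' @param init_window_s seconds of presumed-static data averaged to
#'   initialize the orientation (tilt-only, yaw = 0). Default 0.5.
#' @return an object of class `fusion_settings`.
#' @export
fusion_settings <- function(beta = 0.1, init_window_s = 0.5) {
  stopifnot(is.numeric(beta), length(beta) == 1, beta >= 0,
            is.numeric(init_window_s), length(init_window_s) == 1,
            init_window_s > 0)
  structure(list(beta = beta, init_window_s = init_window_s),
            class = "fusion_settings")
}

#' One Madgwick filter update
#'
#' Advances a unit quaternion by one sampling interval: the quaternion rate
#' from the gyroscope is corrected by the normalized objective-function
#' gradient that aligns the predicted gravity direction with the measured
#' accelerometer direction, scaled by `beta`. When the accelerometer vector
#' is zero the correction is skipped and only gyro propagation applies. Only
#' the accelerometer direction is used, so the update is invariant to a
#' positive rescaling of `accel`.
#'
#' @param q current unit quaternion `c(w, x, y, z)`.
#' @param gyro angular rate 3-vector in deg/s (sensor frame).
#' @param accel specific-force 3-vector in g (sensor frame).
#' @param dt time step in seconds, > 0.
#' @param beta filter gain, >= 0.
#' @return the updated unit quaternion (renormalized every step).
#' @export
#' @examples
#' q <- c(1, 0, 0, 0)
#' madgwick_update(q, gyro = c(0, 10, 0), accel = c(0, 0, 1), dt = 1 / 52)
madgwick_update <- function(q, gyro, accel, dt, beta = 0.1) {
  if (!all(is.finite(q), is.finite(gyro), is.finite(accel), is.finite(dt))) {
    stop("non-finite input to madgwick_update")
  }
  stopifnot(dt > 0, beta >= 0, length(q) == 4, length(gyro) == 3,
            length(accel) == 3)
  g <- gyro * DEG2RAD
  qdot <- 0.5 * quat_multiply(q, c(0, g))

  anorm <- sqrt(sum(accel^2))
  if (anorm > 0 && beta > 0) {
    a <- accel / anorm
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    # objective: predicted gravity (sensor frame, z-up Earth) minus measured
    f1 <- 2 * (x * z - w * y) - a[1]
    f2 <- 2 * (w * x + y * z) - a[2]
    f3 <- 2 * (0.5 - x * x - y * y) - a[3]
    s <- c(-2 * y * f1 + 2 * x * f2,
            2 * z * f1 + 2 * w * f2 - 4 * x * f3,
           -2 * w * f1 + 2 * z * f2 - 4 * y * f3,
            2 * x * f1 + 2 * y * f2)
    snorm <- sqrt(sum(s * s))
    if (snorm > 0) qdot <- qdot - beta * (s / snorm)
  }
  quat_normalize(q + qdot * dt)
}

#' Estimate an orientation trace for one IMU stream
#'
#' Runs the Madgwick filter over a stream of samples. The initial quaternion
#' is the tilt (yaw = 0) implied by the mean accelerometer vector over the
#' first `init_window_s` seconds, so recordings that begin at rest carry no
#' convergence transient into the angle traces. Time steps are taken from
#' consecutive timestamps, not from the nominal rate.
#'
#' @param stream an IMU stream: data frame with columns
#'   `t, ax, ay, az, gx, gy, gz` (seconds, g, deg/s), as held in a
#'   [dual_imu_recording()].
#' @param settings a [fusion_settings()] object.
#' @return an n-by-4 matrix of unit quaternions (columns `w, x, y, z`), one
#'   row per sample, with the timestamps in attribute `t`.
#' @export
estimate_orientation <- function(stream, settings = fusion_settings()) {
  stream <- as_imu_stream(stream)
  n <- nrow(stream)
  if (n < 2) stop("insufficient data: need at least 2 samples")
  if (any(diff(stream$t) <= 0)) {
    stop("integrity error: timestamps not strictly increasing")
  }
  acc <- as.matrix(stream[, c("ax", "ay", "az")])
  gyr <- as.matrix(stream[, c("gx", "gy", "gz")])
  t <- stream$t

  in_win <- t <= t[1] + settings$init_window_s
  if (!any(in_win)) in_win[1] <- TRUE
  q <- tilt_from_accel(colMeans(acc[in_win, , drop = FALSE]))

  out <- matrix(NA_real_, n, 4, dimnames = list(NULL, c("w", "x", "y", "z")))
  out[1, ] <- q
  beta <- settings$beta
  for (i in 2:n) {
    q <- madgwick_update(q, gyr[i, ], acc[i, ], t[i] - t[i - 1], beta)
    out[i, ] <- q
  }
  attr(out, "t") <- t
  out
}

#' Euler-angle trace for one IMU stream
#'
#' Convenience wrapper: [estimate_orientation()] followed by
#' [quaternion_to_euler()] row by row.
#'
#' @inheritParams estimate_orientation
#' @return data frame with columns `t, yaw, pitch, roll` (degrees).
#' @export
estimate_euler <- function(stream, settings = fusion_settings()) {
  q <- estimate_orientation(stream, settings)
  e <- quaternion_to_euler(q)
  data.frame(t = attr(q, "t"), yaw = e[, "yaw"], pitch = e[, "pitch"],
             roll = e[, "roll"])
}
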