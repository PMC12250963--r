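#' Sensor calibration: gyro bias and six-position accelerometer correction
#'
#' The gyroscope bias is the time average of a static stream. The
#' accelerometer is calibrated from six static placements, one per
#' face-up/face-down orientation of each axis: with `m+` the mean reading
#' when an axis points up and `m-` when it points down,
#' `offset = (m+ + m-) / 2` and `scale = (m+ - m-) / 2`, so the corrected
#' readings map to exactly +1 g and -1 g. Cross-axis misalignment is not
#' identifiable from six static placements and is not modeled.
#'
#' @name calibration
NULL

#' Calibration parameters for one IMU
#'
#' @param gyro_bias 3-vector, deg/s.
#' @param accel_offset 3-vector, g.
#' @param accel_scale 3-vector, dimensionless, strictly positive.
#' @return an object of class `calibration_params`.
#' @export
calibration_params <- function(gyro_bias = c(0, 0, 0),
                               accel_offset = c(0, 0, 0),
                               accel_scale = c(1, 1, 1)) {
  gyro_bias <- as.numeric(gyro_bias)
  accel_offset <- as.numeric(accel_offset)
  accel_scale <- as.numeric(accel_scale)
  stopifnot(length(gyro_bias) == 3, length(accel_offset) == 3,
            length(accel_scale) == 3)
  if (any(!is.finite(c(gyro_bias, accel_offset, accel_scale)))) {
    stop("non-finite calibration parameters")
  }
  if (any(accel_scale <= 0)) stop("accel_scale components must be positive")
  structure(list(gyro_bias = gyro_bias, accel_offset = accel_offset,
                 accel_scale = accel_scale),
            class = "calibration_params")
}

#' @export
print.calibration_params <- function(x, ...) {
  cat("<calibration_params>\n")
  cat("  gyro_bias (deg/s):", paste(signif(x$gyro_bias, 5), collapse = ", "), "\n")
  cat("  accel_offset (g): ", paste(signif(x$accel_offset, 5), collapse = ", "), "\n")
  cat("  accel_scale:      ", paste(signif(x$accel_scale, 5), collapse = ", "), "\n")
  invisible(x)
}

#' Estimate gyroscope bias from a static stream
#'
#' Averages the gyro readings of a stream recorded on a stable, non-rotating
#' surface. A motion check rejects streams whose per-axis gyro standard
#' deviation exceeds `max_sd` — generous for a resting surface, strict
#' against limb motion.
#'
#' @param static_samples an [imu_stream()] (or data frame with the stream
#'   columns) assumed static.
#' @param max_sd motion-check threshold in deg/s, default 2.
#' @return 3-vector of per-axis bias in deg/s.
#' @export
estimate_gyro_bias <- function(static_samples, max_sd = 2) {
  s <- as_imu_stream(static_samples)
  if (nrow(s) == 0) stop("insufficient data: empty static stream")
  g <- as.matrix(s[c("gx", "gy", "gz")])
  if (nrow(g) >= 2) {
    sds <- apply(g, 2, stats::sd)
    bad <- which(sds > max_sd)
    if (length(bad) > 0) {
      stop("not static: gyro SD on axis ", c("x", "y", "z")[bad[1]],
           " is ", signif(sds[bad[1]], 4), " deg/s (limit ", max_sd, ")")
    }
  }
  unname(colMeans(g))
}

#' Estimate accelerometer offset and scale from six static placements
#'
#' @param orientations list of exactly six [imu_stream()]s, one per
#'   face-up/face-down placement of each axis, in any order. The gravity
#'   axis of each stream is identified as the largest-magnitude mean
#'   accelerometer component.
#' @return list with `accel_offset` and `accel_scale` 3-vectors (g and
#'   dimensionless).
#' @export
estimate_accel_calibration <- function(orientations) {
  if (!is.list(orientations) || length(orientations) != 6) {
    stop("coverage error: exactly six static placements required, got ",
         length(orientations))
  }
  means <- matrix(NA_real_, 3, 2,
                  dimnames = list(c("x", "y", "z"), c("up", "down")))
  for (s in orientations) {
    s <- as_imu_stream(s)
    if (nrow(s) == 0) stop("insufficient data: empty placement stream")
    m <- colMeans(as.matrix(s[c("ax", "ay", "az")]))
    axis <- which.max(abs(m))
    side <- if (m[axis] > 0) "up" else "down"
    if (!is.na(means[axis, side])) {
      stop("duplication error: two placements claim ",
           c("+", "-")[(side == "down") + 1], c("x", "y", "z")[axis], " up")
    }
    means[axis, side] <- m[axis]
  }
  miss <- which(is.na(means), arr.ind = TRUE)
  if (nrow(miss) > 0) {
    stop("coverage error: missing placement ",
         c("+", "-")[(miss[1, 2] == 2) + 1], rownames(means)[miss[1, 1]],
         " up")
  }
  offset <- (means[, "up"] + means[, "down"]) / 2
  scale <- (means[, "up"] - means[, "down"]) / 2
  list(accel_offset = unname(offset), accel_scale = unname(scale))
}

#' Apply calibration corrections to a recording
#'
#' Per sample: `gyro' = gyro - gyro_bias`;
#' `accel'_k = (accel_k - accel_offset_k) / accel_scale_k`. Timestamps and
#' metadata are unchanged. With identity parameters this is the identity
#' map, and the transformation is invertible given the parameters.
#'
#' @param rec a [dual_imu_recording()].
#' @param proximal_params,distal_params [calibration_params()] for each
#'   unit.
#' @return the corrected [dual_imu_recording()].
#' @export
apply_calibration <- function(rec, proximal_params,
                              distal_params = proximal_params) {
  stopifnot(inherits(rec, "dual_imu_recording"),
            inherits(proximal_params, "calibration_params"),
            inherits(distal_params, "calibration_params"))
  rec$proximal <- apply_params_stream(rec$proximal, proximal_params)
  rec$distal <- apply_params_stream(rec$distal, distal_params)
  rec
}

apply_params_stream <- function(stream, params) {
  for (k in 1:3) {
    ac <- c("ax", "ay", "az")[k]
    gc <- c("gx", "gy", "gz")[k]
    stream[[ac]] <- (stream[[ac]] - params$accel_offset[k]) /
      params$accel_scale[k]
    stream[[gc]] <- stream[[gc]] - params$gyro_bias[k]
  }
  stream
}

#' Serialize / deserialize calibration parameters as JSON
#'
#' @param params a [calibration_params()].
#' @param path JSON file path.
#' @return [write_calibration_params()] returns `path` invisibly;
#'   [read_calibration_params()] returns a [calibration_params()].
#' @export
write_calibration_params <- function(params, path) {
  jsonlite::write_json(
    list(gyro_bias = params$gyro_bias, accel_offset = params$accel_offset,
         accel_scale = params$accel_scale),
    path, digits = NA)
  invisible(path)
}

#' @rdname write_calibration_params
#' @export
read_calibration_params <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  calibration_params(x$gyro_bias, x$accel_offset, x$accel_scale)
}
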