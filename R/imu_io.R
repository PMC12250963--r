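#' Dual-IMU recordings: data model and CSV log I/O
#'
#' A recording holds two synchronous 6-DoF streams sampled by a single
#' microcontroller: a proximal unit (Main Board) above the joint and a
#' distal unit (Small Board) below it. The CSV log dialect is one row per
#' synchronized sample pair with a fixed header
#' `t,ax_p,ay_p,az_p,gx_p,gy_p,gz_p,ax_d,ay_d,az_d,gx_d,gy_d,gz_d`
#' (accelerometer in g, gyroscope in deg/s, time in seconds); recording
#' metadata travels in a sidecar JSON file with the same stem.
#'
#' @name imu_io
NULL

ACCEL_FULL_SCALE_G <- 8      # sensor accelerometer full scale, g
GYRO_FULL_SCALE_DPS <- 1000  # sensor gyroscope full scale, deg/s

IMU_COLS <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
CSV_COLS <- c("t",
              paste0(c("ax", "ay", "az", "gx", "gy", "gz"), "_p"),
              paste0(c("ax", "ay", "az", "gx", "gy", "gz"), "_d"))

#' Construct a single-IMU stream
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param accel n-by-3 matrix (or 3-column data frame) of accelerometer
#'   readings in g.
#' @param gyro n-by-3 matrix of gyroscope readings in deg/s.
#' @return a data frame of class `imu_stream` with columns
#'   `t, ax, ay, az, gx, gy, gz`.
#' @export
imu_stream <- function(t, accel, gyro) {
  accel <- matrix(as.numeric(as.matrix(accel)), ncol = 3)
  gyro <- matrix(as.numeric(as.matrix(gyro)), ncol = 3)
  stopifnot(length(t) == nrow(accel), nrow(accel) == nrow(gyro))
  df <- data.frame(t = as.numeric(t),
                   ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                   gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3])
  validate_imu_stream(df)
  class(df) <- c("imu_stream", "data.frame")
  df
}

as_imu_stream <- function(x) {
  if (!all(IMU_COLS %in% names(x))) {
    stop("format error: stream must have columns ",
         paste(IMU_COLS, collapse = ", "))
  }
  as.data.frame(x)[IMU_COLS]
}

validate_imu_stream <- function(df) {
  if (nrow(df) == 0) return(invisible(df))
  vals <- as.matrix(df[IMU_COLS])
  if (any(!is.finite(vals))) stop("non-finite values in IMU stream")
  acc <- abs(as.matrix(df[c("ax", "ay", "az")]))
  if (any(acc > ACCEL_FULL_SCALE_G + 1e-9)) {
    stop("accelerometer reading exceeds full scale (", ACCEL_FULL_SCALE_G,
         " g)")
  }
  gyr <- abs(as.matrix(df[c("gx", "gy", "gz")]))
  if (any(gyr > GYRO_FULL_SCALE_DPS + 1e-9)) {
    stop("gyroscope reading exceeds full scale (", GYRO_FULL_SCALE_DPS,
         " deg/s)")
  }
  invisible(df)
}

#' Construct a dual-IMU recording
#'
#' @param proximal,distal [imu_stream()]s (or data frames with the stream
#'   columns) from the proximal and distal units. They must share identical
#'   timestamps: both sensors are read by one microcontroller over I2C.
#' @param rate_hz nominal sampling rate, default 52.
#' @param joint `"knee"` or `"ankle"`.
#' @param condition `"bare"` or `"banded"` (with or without the compression
#'   bandage over the units).
#' @param meta named list of free-form annotations.
#' @return an object of class `dual_imu_recording`.
#' @export
dual_imu_recording <- function(proximal, distal, rate_hz = 52,
                               joint = c("knee", "ankle"),
                               condition = c("bare", "banded"),
                               meta = list()) {
  joint <- match.arg(joint)
  condition <- match.arg(condition)
  proximal <- as_imu_stream(proximal)
  distal <- as_imu_stream(distal)
  stopifnot(is.numeric(rate_hz), length(rate_hz) == 1, rate_hz > 0)
  if (nrow(proximal) != nrow(distal)) {
    stop("integrity error: proximal and distal streams differ in length")
  }
  if (nrow(proximal) > 0 && any(proximal$t != distal$t)) {
    stop("integrity error: proximal and distal timestamps differ")
  }
  validate_imu_stream(proximal)
  validate_imu_stream(distal)
  if (nrow(proximal) >= 2) {
    dt <- diff(proximal$t)
    bad <- which(dt <= 0)
    if (length(bad) > 0) {
      stop("integrity error: timestamps not strictly increasing at row ",
           bad[1])
    }
    med <- stats::median(dt)
    if (abs(med - 1 / rate_hz) > 0.1 / rate_hz) {
      stop("integrity error: median sampling interval ", signif(med, 4),
           " s is not within 10% of 1/", rate_hz, " s")
    }
  }
  structure(list(proximal = proximal, distal = distal, rate_hz = rate_hz,
                 joint = joint, condition = condition, meta = meta),
            class = "dual_imu_recording")
}

#' @export
print.dual_imu_recording <- function(x, ...) {
  n <- nrow(x$proximal)
  dur <- if (n > 1) x$proximal$t[n] - x$proximal$t[1] else 0
  cat(sprintf(
    "<dual_imu_recording> %d samples @ %g Hz (%.1f s), joint=%s, condition=%s\n",
    n, x$rate_hz, dur, x$joint, x$condition))
  invisible(x)
}

#' @export
length.dual_imu_recording <- function(x) nrow(x$proximal)

#' Construct an angle series
#'
#' @param t timestamps in seconds, strictly increasing.
#' @param angle angles in degrees.
#' @param source `"device"` or `"reference"`.
#' @return a data frame of class `angle_series` with columns `t, angle` and
#'   attribute `source`.
#' @export
angle_series <- function(t, angle, source = c("device", "reference")) {
  source <- match.arg(source)
  t <- as.numeric(t); angle <- as.numeric(angle)
  if (length(t) != length(angle)) stop("t and angle lengths differ")
  if (any(!is.finite(t)) || any(!is.finite(angle))) {
    stop("non-finite values in angle series")
  }
  if (length(t) >= 2 && any(diff(t) <= 0)) {
    stop("integrity error: timestamps not strictly increasing")
  }
  structure(data.frame(t = t, angle = angle),
            source = source, class = c("angle_series", "data.frame"))
}

#' Read a dual-IMU recording from a CSV log
#'
#' Reads the CSV dialect described in [imu_io] plus an optional sidecar
#' `<stem>.json` holding `rate_hz`, `joint` and `condition`. Rows containing
#' any non-finite field are dropped with a warning.
#'
#' @param path path to the CSV file.
#' @param rate_hz nominal sampling rate; overridden by the sidecar when one
#'   is present.
#' @param joint,condition defaults when no sidecar is present.
#' @return a [dual_imu_recording()].
#' @export
read_recording <- function(path, rate_hz = 52, joint = "knee",
                           condition = "bare") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  missing_cols <- setdiff(CSV_COLS, names(df))
  if (length(missing_cols) > 0) {
    stop("format error: missing column(s) ",
         paste(missing_cols, collapse = ", "))
  }
  extra <- setdiff(names(df), CSV_COLS)
  if (length(extra) > 0) {
    stop("format error: unexpected column(s) ", paste(extra, collapse = ", "))
  }
  df <- df[CSV_COLS]
  if (nrow(df) > 0) {
    ok <- apply(is.finite(as.matrix(df)), 1, all)
    if (any(!ok)) {
      warning(sum(!ok), " row(s) with non-finite fields dropped")
      df <- df[ok, , drop = FALSE]
    }
    bad <- which(diff(df$t) <= 0)
    if (length(bad) > 0) {
      stop("integrity error: timestamps not strictly increasing at row ",
           bad[1])
    }
  }
  sidecar <- sidecar_path(path)
  meta <- list()
  if (file.exists(sidecar)) {
    side <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    if (!is.null(side$rate_hz)) rate_hz <- side$rate_hz
    if (!is.null(side$joint)) joint <- side$joint
    if (!is.null(side$condition)) condition <- side$condition
    meta <- side$meta %||% list()
  }
  p <- df[c("t", paste0(c("ax", "ay", "az", "gx", "gy", "gz"), "_p"))]
  d <- df[c("t", paste0(c("ax", "ay", "az", "gx", "gy", "gz"), "_d"))]
  names(p) <- names(d) <- IMU_COLS
  dual_imu_recording(p, d, rate_hz = rate_hz, joint = joint,
                     condition = condition, meta = meta)
}

#' Write a dual-IMU recording to a CSV log
#'
#' Values round-trip through [read_recording()] to within 1e-9 (15
#' significant digits are written). A sidecar `<stem>.json` records
#' `rate_hz`, `joint`, `condition` and `meta`.
#'
#' @param rec a [dual_imu_recording()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "dual_imu_recording"))
  p <- rec$proximal; d <- rec$distal
  out <- data.frame(t = p$t,
                    p$ax, p$ay, p$az, p$gx, p$gy, p$gz,
                    d$ax, d$ay, d$az, d$gx, d$gy, d$gz)
  names(out) <- CSV_COLS
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(CSV_COLS, collapse = ","), con)
  if (nrow(out) > 0) {
    lines <- do.call(paste, c(lapply(out, format_num), list(sep = ",")))
    writeLines(lines, con)
  }
  jsonlite::write_json(
    list(rate_hz = rec$rate_hz, joint = rec$joint,
         condition = rec$condition, meta = rec$meta),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

format_num <- function(x) formatC(x, digits = 15, format = "g")

sidecar_path <- function(path) paste0(sub("\\.[Cc][Ss][Vv]$", "", path), ".json")

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read / write an angle series CSV (`t,angle_deg`)
#'
#' @param path CSV path.
#' @param source series provenance, `"device"` or `"reference"`.
#' @return [read_angle_series()] returns an [angle_series()];
#'   [write_angle_series()] returns `path` invisibly.
#' @export
read_angle_series <- function(path, source = "device") {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path)
  if (!all(c("t", "angle_deg") %in% names(df))) {
    stop("format error: expected columns t, angle_deg")
  }
  angle_series(df$t, df$angle_deg, source = source)
}

#' @param series an [angle_series()].
#' @rdname read_angle_series
#' @export
write_angle_series <- function(series, path) {
  df <- data.frame(t = format_num(series$t),
                   angle_deg = format_num(series$angle))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Resample an angle series to a uniform rate
#'
#' Linear interpolation onto a uniform grid at `target_hz` spanning the
#' input's time range; no extrapolation beyond the input span. Intended to
#' bring a 52 Hz device trace and a 100 Hz optoelectronic reference onto a
#' common timebase before agreement analysis.
#'
#' @param series an [angle_series()] with at least 2 samples.
#' @param target_hz target sampling rate, > 0.
#' @return a resampled [angle_series()] with the same `source`.
#' @export
resample_series <- function(series, target_hz) {
  stopifnot(is.numeric(target_hz), length(target_hz) == 1, target_hz > 0)
  if (nrow(series) < 2) stop("insufficient data: need at least 2 samples")
  grid <- seq(series$t[1], series$t[nrow(series)], by = 1 / target_hz)
  vals <- stats::approx(series$t, series$angle, xout = grid)$y
  angle_series(grid, vals, source = attr(series, "source") %||% "device")
}
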