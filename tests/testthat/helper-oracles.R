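# Independent oracles and small fixture builders used across the suite.
# The oracles evaluate the defining formulas directly (sums, closed forms)
# and never call the package functions they check.

# angular distance in degrees between two unit quaternions
quat_angle_deg <- function(qa, qb) {
  d <- abs(sum(qa * qb))
  2 * acos(min(1, d)) * 180 / pi
}

# closed-form quaternion for a constant body rate (deg/s) applied for t_s
quat_constant_rate <- function(rate_dps, t_s) {
  w <- rate_dps * pi / 180
  wn <- sqrt(sum(w^2))
  if (wn == 0) return(c(1, 0, 0, 0))
  axis <- w / wn
  half <- wn * t_s / 2
  c(cos(half), sin(half) * axis)
}

# brute-force OLS of y on x from the normal-equation sums
ols_oracle <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y)
  m <- (n * sum(x * y) - sx * sy) / (n * sum(x * x) - sx^2)
  q <- sy / n - m * sx / n
  r <- (n * sum(x * y) - sx * sy) /
    sqrt((n * sum(x * x) - sx^2) * (n * sum(y * y) - sy^2))
  list(m = m, q = q, r2 = r^2)
}

# brute-force Bland-Altman from the definition (gold - device, n-1 SD)
ba_oracle <- function(gold, device) {
  d <- gold - device
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  list(ba_mean = m, ba_sd = s, ba_loa = c(m - 1.96 * s, m + 1.96 * s))
}

# brute-force percentage error
pe_oracle <- function(gold, device) {
  v <- 100 * abs(device - gold) / abs(gold)
  n <- length(v)
  m <- sum(v) / n
  list(pct_error_mean = m,
       pct_error_sd = sqrt(sum((v - m)^2) / (n - 1)))
}

# small well-formed recording fixture (pure construction, no simulator)
tiny_recording <- function(n = 52, rate = 52) {
  t <- (0:(n - 1)) / rate
  mk <- function(off) imu_stream(
    t,
    accel = cbind(0.01 * sin(t) + off, 0.02 * cos(t), sqrt(
      pmax(0, 1 - (0.01 * sin(t) + off)^2 - (0.02 * cos(t))^2))),
    gyro = cbind(5 * sin(3 * t), -4 * cos(2 * t), 0.5 + 0 * t))
  dual_imu_recording(mk(0), mk(0.005), rate_hz = rate)
}
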