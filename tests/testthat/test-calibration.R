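static_stream <- function(gyro = c(0, 0, 0), accel = c(0, 0, 1), n = 52,
                          gyro_noise = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  g <- matrix(gyro, n, 3, byrow = TRUE)
  if (gyro_noise > 0) g <- g + matrix(rnorm(3 * n, 0, gyro_noise), n, 3)
  imu_stream((0:(n - 1)) / 52, matrix(accel, n, 3, byrow = TRUE), g)
}

test_that("gyro bias is the per-axis mean of a static stream", {
  expect_equal(estimate_gyro_bias(static_stream(c(1, -0.5, 0.2))),
               c(1, -0.5, 0.2))
  expect_equal(estimate_gyro_bias(static_stream(c(0, 0, 0))), c(0, 0, 0))
  expect_error(estimate_gyro_bias(static_stream()[0, ]), "insufficient")
})

test_that("gyro bias recovery under noise is within 3 standard errors", {
  n <- 5200; sigma <- 0.1
  s <- static_stream(c(0.7, 0, 0), n = n, gyro_noise = sigma, seed = 7)
  bias <- estimate_gyro_bias(s)
  expect_lt(abs(bias[1] - 0.7), 3 * sigma / sqrt(n))
})

test_that("the motion check rejects non-static streams and names the axis", {
  s <- static_stream(n = 52)
  s$gy <- 30 * sin(2 * pi * (1:52) / 52)
  expect_error(estimate_gyro_bias(s), "axis y")
})

test_that("six-position accelerometer calibration matches the pairing formulas", {
  # ideal: identity calibration
  fix <- six_position_fixtures()
  cal <- estimate_accel_calibration(fix)
  expect_equal(cal$accel_offset, c(0, 0, 0), tolerance = 1e-12)
  expect_equal(cal$accel_scale, c(1, 1, 1), tolerance = 1e-12)

  # hand arithmetic: +1.05 / -0.95 on x -> offset 0.05, scale 1.0
  fix2 <- six_position_fixtures(accel_offset = c(0.05, 0, 0))
  cal2 <- estimate_accel_calibration(fix2)
  expect_equal(cal2$accel_offset[1], 0.05)
  expect_equal(cal2$accel_scale[1], 1.0)

  # hand arithmetic: +-1.10 on x -> offset 0, scale 1.10
  fix3 <- six_position_fixtures(accel_scale = c(1.10, 1, 1))
  cal3 <- estimate_accel_calibration(fix3)
  expect_equal(cal3$accel_offset[1], 0)
  expect_equal(cal3$accel_scale[1], 1.10)

  # corrected readings map to exactly +-1 g
  p <- calibration_params(accel_offset = cal3$accel_offset,
                          accel_scale = cal3$accel_scale)
  corrected <- (1.10 - p$accel_offset[1]) / p$accel_scale[1]
  expect_equal(corrected, 1.0)
})

test_that("placement coverage and duplication are diagnosed", {
  fix <- six_position_fixtures()
  expect_error(estimate_accel_calibration(fix[1:5]), "six")
  fix_dup <- fix; fix_dup[[2]] <- fix_dup[[1]]  # two +x-up placements
  expect_error(estimate_accel_calibration(fix_dup), "duplication")
  expect_error(estimate_accel_calibration(c(fix_dup[2:6], fix_dup[1])),
               "duplication")
})

test_that("apply_calibration corrects readings and is invertible", {
  rec <- tiny_recording()
  idp <- calibration_params()
  expect_equal(apply_calibration(rec, idp, idp), rec)

  p <- calibration_params(gyro_bias = c(1, 1, 1))
  rec2 <- rec
  rec2$proximal[c("gx", "gy", "gz")] <-
    rec2$proximal[c("gx", "gy", "gz")] + 1
  rec2$distal[c("gx", "gy", "gz")] <- rec2$distal[c("gx", "gy", "gz")] + 1
  expect_equal(apply_calibration(rec2, p, p), rec)

  # accel x = 1.10 g with offset 0, scale 1.10 -> 1.0 g
  s <- static_stream(accel = c(1.10, 0, 0))
  r <- dual_imu_recording(s, s)
  pc <- calibration_params(accel_scale = c(1.10, 1, 1))
  out <- apply_calibration(r, pc, pc)
  expect_equal(out$proximal$ax, rep(1, 52))
})

test_that("estimate-then-apply recovers injected errors end to end", {
  offset <- c(0.05, 0, -0.02); scale <- c(1.1, 1.0, 0.95)
  bias <- c(0.7, -0.3, 0.2)

  # noise-free: exact recovery
  fix <- six_position_fixtures(offset, scale)
  cal <- estimate_accel_calibration(fix)
  expect_equal(cal$accel_offset, offset, tolerance = 1e-9)
  expect_equal(cal$accel_scale, scale, tolerance = 1e-9)

  sim <- simulate_motion(simulation_config("static", gyro_bias = bias))
  expect_equal(estimate_gyro_bias(sim$recording$proximal), bias,
               tolerance = 1e-9)

  # noisy: within 3 standard errors of the sample mean
  nsd <- 0.01; n <- 260
  fixn <- six_position_fixtures(offset, scale, noise_sd = nsd,
                                n_samples = n, seed = 11)
  caln <- estimate_accel_calibration(fixn)
  # offset/scale are half-sums/differences of two means, each with SE
  # scale*nsd/sqrt(n); the combination has SE scale*nsd/sqrt(2n)
  se <- scale * nsd / sqrt(2 * n)
  expect_true(all(abs(caln$accel_offset - offset) < 3 * se))
  expect_true(all(abs(caln$accel_scale - scale) < 3 * se))
})

test_that("calibration params serialize to JSON and back", {
  p <- calibration_params(c(0.7, -0.3, 0.2), c(0.05, 0, -0.02),
                          c(1.1, 1, 0.95))
  path <- withr::local_tempfile(fileext = ".json")
  write_calibration_params(p, path)
  back <- read_calibration_params(path)
  expect_equal(back, p)
  expect_error(calibration_params(accel_scale = c(1, -1, 1)), "positive")
})
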