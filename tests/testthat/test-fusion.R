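test_that("quaternion-Euler conversions match closed forms", {
  expect_equal(quaternion_to_euler(c(1, 0, 0, 0)),
               c(yaw = 0, pitch = 0, roll = 0))
  # 90 deg about y
  e <- quaternion_to_euler(c(sqrt(2) / 2, 0, sqrt(2) / 2, 0))
  expect_equal(unname(e["pitch"]), 90)
  # 45 deg about x
  e2 <- quaternion_to_euler(c(cos(pi / 8), sin(pi / 8), 0, 0))
  expect_equal(unname(e2["roll"]), 45)
  expect_equal(unname(e2["pitch"]), 0)
  expect_equal(unname(e2["yaw"]), 0)
  expect_error(quaternion_to_euler(c(2, 0, 0, 0)), "norm")
})

test_that("euler_to_quaternion inverts quaternion_to_euler away from gimbal lock", {
  set.seed(42)
  for (i in 1:50) {
    yaw <- runif(1, -179, 179)
    pitch <- runif(1, -85, 85)
    roll <- runif(1, -179, 179)
    q <- euler_to_quaternion(yaw, pitch, roll)
    e <- quaternion_to_euler(q)
    expect_equal(unname(e), c(yaw, pitch, roll), tolerance = 1e-9)
  }
})

test_that("identity orientation with gravity along +z is a filter fixed point", {
  q <- c(1, 0, 0, 0)
  for (i in 1:20) q <- madgwick_update(q, c(0, 0, 0), c(0, 0, 1), 1 / 52)
  expect_equal(q, c(1, 0, 0, 0), tolerance = 1e-12)
})

test_that("with beta = 0 the filter reduces to gyro integration", {
  # constant 90 deg/s about y for 1 s -> 90 deg rotation, small-step error
  q <- c(1, 0, 0, 0)
  for (i in 1:52) {
    q <- madgwick_update(q, c(0, 90, 0), c(0, 0, 1), 1 / 52, beta = 0)
  }
  oracle <- quat_constant_rate(c(0, 90, 0), 1)
  expect_lt(quat_angle_deg(q, oracle), 0.2)

  # arbitrary constant rate against the closed-form integral
  rate <- c(30, -50, 20)
  q <- c(1, 0, 0, 0)
  for (i in 1:104) {
    q <- madgwick_update(q, rate, c(0, 0, 0), 1 / 52, beta = 0)
  }
  expect_lt(quat_angle_deg(q, quat_constant_rate(rate, 2)), 0.5)
})

test_that("static accelerometer input pulls pitch to the tilt angle", {
  # start from the identity, gravity consistent with pitch = 30 deg
  accel <- c(-sin(30 * pi / 180), 0, cos(30 * pi / 180))
  q <- c(1, 0, 0, 0)
  for (i in 1:(52 * 10)) {
    q <- madgwick_update(q, c(0, 0, 0), accel, 1 / 52, beta = 0.1)
  }
  expect_lt(abs(quaternion_to_euler(q)["pitch"] - 30), 0.5)
})

test_that("noise-free convergence to static tilt is monotone in error", {
  accel <- c(-sin(20 * pi / 180), 0, cos(20 * pi / 180))
  q <- c(1, 0, 0, 0)
  errs <- numeric(20)
  for (k in 1:20) {
    for (i in 1:26) q <- madgwick_update(q, c(0, 0, 0), accel, 1 / 52)
    errs[k] <- abs(quaternion_to_euler(q)["pitch"] - 20)
  }
  # monotone decrease down to the fixed-step floor (~beta * dt per update)
  floor_deg <- 0.1 / 52 * 180 / pi
  expect_true(all(diff(errs) <= 1e-9 | errs[-1] < 2 * floor_deg))
  expect_lt(errs[20], 2 * floor_deg)
})

test_that("the update uses only the accelerometer direction", {
  q0 <- euler_to_quaternion(10, 20, 5)
  a <- c(-0.3, 0.1, 0.9)
  q1 <- madgwick_update(q0, c(5, -3, 2), a, 1 / 52)
  q2 <- madgwick_update(q0, c(5, -3, 2), 3.7 * a, 1 / 52)
  expect_equal(q1, q2, tolerance = 1e-12)
  # zero accelerometer: gyro propagation only
  q3 <- madgwick_update(q0, c(5, -3, 2), c(0, 0, 0), 1 / 52)
  q4 <- madgwick_update(q0, c(5, -3, 2), c(0, 0, 0), 1 / 52, beta = 0)
  expect_equal(q3, q4)
})

test_that("quaternion norm is conserved across long update sequences", {
  set.seed(1)
  q <- euler_to_quaternion(0, 10, 0)
  worst <- 0
  for (i in 1:5000) {
    q <- madgwick_update(q, rnorm(3, 0, 50), rnorm(3, c(0, 0, 1), 0.05),
                         1 / 52)
    worst <- max(worst, abs(sqrt(sum(q^2)) - 1))
  }
  expect_lt(worst, 1e-6)
})

test_that("orientation estimation recovers static tilt and sinusoidal pitch", {
  # fully static stream at a known tilt: pitch/roll exact after 1 s
  sim <- simulate_motion(simulation_config("static", static_pitch_deg = 25,
                                           duration_s = 5))
  e <- estimate_euler(sim$recording$proximal)
  late <- e$t > 1
  expect_true(all(abs(e$pitch[late] - 25) < 0.5))
  expect_true(all(abs(e$roll[late]) < 0.5))

  # sinusoidal-like hinge motion: distal pitch trace vs ground truth
  sim2 <- simulate_motion(simulation_config("flexion_extension",
                                            fe_amplitude = 45,
                                            distal_share = 1))
  e2 <- estimate_euler(sim2$recording$distal)
  rmse <- sqrt(mean((e2$pitch - sim2$truth$pitch_distal)^2))
  expect_lt(rmse, 2)

  expect_error(estimate_orientation(sim$recording$proximal[1, ]),
               "insufficient")
  bad <- sim$recording$proximal[1:10, ]
  bad$t[5] <- bad$t[4]
  expect_error(estimate_orientation(bad), "integrity")
})
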