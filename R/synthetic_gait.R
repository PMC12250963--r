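#' Ground-truth simulator of two-segment hinge motion
#'
#' Emulates the dual-IMU device worn across a hinge joint: the proximal and
#' distal segments each follow a programmed sagittal pitch trajectory, and
#' the simulator emits the exact body-frame angular rates and
#' gravity-direction accelerometer readings those trajectories imply,
#' optionally corrupted by Gaussian noise and injected bias/offset/scale
#' errors. The clean trajectories, orientations and gait event times are
#' returned as ground truth, so every pipeline stage can be validated
#' without hardware.
#'
#' Scenarios:
#' * `static` — both units at rest at a fixed pitch.
#' * `flexion_extension` — raised-cosine joint-angle repetitions
#'   (0 to `fe_amplitude` and back), amplitude split between segments.
#' * `walk` — a periodic foot-pitch template (two harmonics, one prominent
#'   swing peak and one pre-swing minimum per gait cycle) on the distal
#'   unit with a small counter-phase shank motion on the proximal unit.
#'
#' @name synthetic_gait
NULL

# walk foot-pitch template on u in [0, 1): one sharp maximum (swing peak,
# g'' = -8 pi^2) at u = 0.25 and one flat quartic minimum (toe-off dwell,
# g'' = 0) at u = 0.75 -- the swing reversal is quick while the foot dwells
# plantarflexed around toe-off, which is why toe-off localizes less
# precisely than the swing peak
walk_template <- function(u) sin(2 * pi * u) - 0.25 * cos(4 * pi * u)
walk_template_d <- function(u) {
  2 * pi * cos(2 * pi * u) * (1 + sin(2 * pi * u))
}
walk_extrema <- function() c(u_max = 0.25, u_min = 0.75)

#' Simulation configuration
#'
#' @param scenario `"static"`, `"flexion_extension"` or `"walk"`.
#' @param duration_s recording length in seconds; when `NULL` it is derived
#'   from the scenario (`n_repetitions / fe_frequency_hz` for
#'   flexion-extension, `n_steps / walk_cadence_hz` for walking, 10 s for
#'   static).
#' @param rate_hz sampling rate, default 52.
#' @param fe_amplitude flexion-extension peak joint angle, degrees
#'   (default 60).
#' @param fe_frequency_hz repetition rate, default 0.5.
#' @param n_repetitions flexion-extension repetitions, default 4 (the
#'   exercise protocol's repetition count).
#' @param walk_cadence_hz gait cycles per second of the instrumented foot.
#'   Presets: 0.93 for the 3 km/h treadmill speed, 1.25 for 5 km/h (see
#'   [walk_preset()]).
#' @param n_steps number of gait cycles, default 20.
#' @param walk_foot_amplitude swing-peak foot pitch, degrees (default 25).
#' @param static_pitch_deg resting pitch of the proximal unit in the static
#'   scenario, default 0.
#' @param lead_in_s seconds of rest before the motion begins (subjects start
#'   each protocol at rest, which is also what the fusion initialization
#'   window assumes); default 1 for the motion scenarios, ignored for
#'   `static`.
#' @param joint `"knee"` or `"ankle"`; sets the default hinge amplitude
#'   split.
#' @param distal_share fraction of the hinge motion carried by the distal
#'   segment; default 0.5 for the knee, 0.8 for the ankle.
#' @param gyro_noise_sd,accel_noise_sd Gaussian measurement noise SD
#'   (deg/s, g), default 0.
#' @param gyro_bias,accel_offset,accel_scale injected sensor errors applied
#'   after noise (both units), recoverable by the calibration module.
#' @param linear_accel add the analytic centripetal/tangential acceleration
#'   of a sensor mounted `seg_length_m` from the hinge (stress test for the
#'   gravity-only fusion assumption); default `FALSE`.
#' @param seg_length_m sensor distance from the hinge axis, metres.
#' @param seed integer seed; identical configurations with identical seeds
#'   produce bit-identical recordings.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(scenario = c("static", "flexion_extension",
                                           "walk"),
                              duration_s = NULL, rate_hz = 52,
                              fe_amplitude = 60, fe_frequency_hz = 0.5,
                              n_repetitions = 4, walk_cadence_hz = 0.93,
                              n_steps = 20, walk_foot_amplitude = 25,
                              static_pitch_deg = 0, lead_in_s = 1,
                              joint = c("knee", "ankle"),
                              distal_share = NULL,
                              gyro_noise_sd = 0, accel_noise_sd = 0,
                              gyro_bias = c(0, 0, 0),
                              accel_offset = c(0, 0, 0),
                              accel_scale = c(1, 1, 1),
                              linear_accel = FALSE, seg_length_m = 0.15,
                              seed = 1) {
  scenario <- match.arg(scenario)
  joint <- match.arg(joint)
  stopifnot(rate_hz > 0, fe_amplitude >= 0, fe_frequency_hz > 0,
            walk_foot_amplitude >= 0, gyro_noise_sd >= 0,
            accel_noise_sd >= 0, seg_length_m > 0)
  if (scenario == "walk" && n_steps < 1) {
    stop("config error: walk scenario requires n_steps >= 1")
  }
  if (scenario == "flexion_extension" && n_repetitions < 1) {
    stop("config error: flexion_extension requires n_repetitions >= 1")
  }
  if (is.null(walk_cadence_hz) || walk_cadence_hz <= 0) {
    stop("config error: walk_cadence_hz must be positive")
  }
  if (is.null(distal_share)) {
    distal_share <- if (joint == "ankle") 0.8 else 0.5
  }
  stopifnot(distal_share >= 0, distal_share <= 1)
  stopifnot(lead_in_s >= 0)
  if (scenario == "static") lead_in_s <- 0
  if (is.null(duration_s)) {
    duration_s <- lead_in_s + switch(scenario,
                         static = 10,
                         flexion_extension = n_repetitions / fe_frequency_hz,
                         walk = n_steps / walk_cadence_hz)
  }
  stopifnot(duration_s > 0)
  structure(list(scenario = scenario, duration_s = duration_s,
                 rate_hz = rate_hz, fe_amplitude = fe_amplitude,
                 fe_frequency_hz = fe_frequency_hz,
                 n_repetitions = n_repetitions,
                 walk_cadence_hz = walk_cadence_hz, n_steps = n_steps,
                 walk_foot_amplitude = walk_foot_amplitude,
                 static_pitch_deg = static_pitch_deg,
                 lead_in_s = lead_in_s, joint = joint,
                 distal_share = distal_share,
                 gyro_noise_sd = gyro_noise_sd,
                 accel_noise_sd = accel_noise_sd,
                 gyro_bias = as.numeric(gyro_bias),
                 accel_offset = as.numeric(accel_offset),
                 accel_scale = as.numeric(accel_scale),
                 linear_accel = linear_accel, seg_length_m = seg_length_m,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

#' Treadmill walk presets
#'
#' Cadence presets for the two treadmill speeds of the validation protocol.
#' The cadences are engineering presets for typical treadmill walking, not
#' measured subject values.
#'
#' @param speed `"3km/h"` or `"5km/h"`.
#' @param ... passed on to [simulation_config()].
#' @return a [simulation_config()] for a walk scenario.
#' @export
walk_preset <- function(speed = c("3km/h", "5km/h"), ...) {
  speed <- match.arg(speed)
  cadence <- if (speed == "3km/h") 0.93 else 1.25
  simulation_config(scenario = "walk", walk_cadence_hz = cadence, ...)
}

#' Simulate a dual-IMU recording with ground truth
#'
#' Generates the programmed segment pitch trajectories for the configured
#' scenario, derives the exact body-frame gyro rates and gravity-direction
#' accelerometer readings, adds measurement noise, applies the injected
#' bias/offset/scale errors, and clips to the sensor full scale (8 g,
#' 1000 deg/s). The returned ground truth holds the clean orientations,
#' joint angle and (for walks) event times.
#'
#' @param config a [simulation_config()].
#' @return list with `recording` (a [dual_imu_recording()]) and `truth`, a
#'   `ground_truth` object with fields `t`, `q_proximal`, `q_distal`
#'   (n-by-4 quaternion matrices), `pitch_proximal`, `pitch_distal`,
#'   `joint_angle` (degrees), `step_peak_t`, `toe_off_t` (walk only) and
#'   `params` (the injected [calibration_params()]).
#' @export
simulate_motion <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  n <- round(config$duration_s * config$rate_hz)
  if (n < 2) stop("config error: duration too short for the sampling rate")
  t <- (0:(n - 1)) / config$rate_hz

  traj <- switch(config$scenario,
    static = {
      th <- rep(config$static_pitch_deg, n)
      list(theta_p = th, theta_d = 0 * th, rate_p = 0 * th, rate_d = 0 * th,
           events = NULL)
    },
    flexion_extension = {
      A <- config$fe_amplitude; f <- config$fe_frequency_hz
      # rest lead-in, then n raised-cosine repetitions, then rest
      tt <- pmin(pmax(t - config$lead_in_s, 0), config$n_repetitions / f)
      th_joint <- A / 2 * (1 - cos(2 * pi * f * tt))
      rate_joint <- A * pi * f * sin(2 * pi * f * tt)
      rate_joint[tt <= 0 | tt >= config$n_repetitions / f] <- 0
      s <- config$distal_share
      list(theta_p = (1 - s) * th_joint, theta_d = s * th_joint,
           rate_p = (1 - s) * rate_joint, rate_d = s * rate_joint,
           events = NULL)
    },
    walk = {
      cad <- config$walk_cadence_hz
      ex <- walk_extrema()
      amp <- config$walk_foot_amplitude / walk_template(ex["u_max"])
      u <- cad * pmax(t - config$lead_in_s, 0)
      moving <- t >= config$lead_in_s
      th_d <- amp * walk_template(u %% 1)
      rate_d <- ifelse(moving, amp * cad * walk_template_d(u %% 1), 0)
      th_p <- 5 * sin(2 * pi * u + pi)
      rate_p <- ifelse(moving, 5 * 2 * pi * cad * cos(2 * pi * u + pi), 0)
      t_end <- t[n]
      k <- 0:(config$n_steps - 1)
      peaks <- config$lead_in_s + (k + ex["u_max"]) / cad
      toes <- config$lead_in_s + (k + ex["u_min"]) / cad
      list(theta_p = th_p, theta_d = th_d, rate_p = rate_p, rate_d = rate_d,
           events = list(step_peak_t = unname(peaks[peaks <= t_end]),
                         toe_off_t = unname(toes[toes <= t_end])))
    })

  params <- calibration_params(config$gyro_bias, config$accel_offset,
                               config$accel_scale)
  streams <- with_seed(config$seed, function() {
    list(p = synth_stream(t, traj$theta_p, traj$rate_p, config),
         d = synth_stream(t, traj$theta_d, traj$rate_d, config))
  })

  rec <- dual_imu_recording(streams$p, streams$d, rate_hz = config$rate_hz,
                            joint = config$joint,
                            meta = list(scenario = config$scenario))
  truth <- structure(list(
    t = t,
    q_proximal = pitch_quaternions(traj$theta_p),
    q_distal = pitch_quaternions(traj$theta_d),
    pitch_proximal = traj$theta_p,
    pitch_distal = traj$theta_d,
    joint_angle = traj$theta_p + traj$theta_d,
    step_peak_t = traj$events$step_peak_t,
    toe_off_t = traj$events$toe_off_t,
    params = params), class = "ground_truth")
  list(recording = rec, truth = truth)
}

pitch_quaternions <- function(theta_deg) {
  half <- theta_deg * DEG2RAD / 2
  cbind(w = cos(half), x = 0, y = sin(half), z = 0)
}

# one unit's measured stream from its pitch trajectory (degrees, deg/s)
synth_stream <- function(t, theta_deg, rate_dps, config) {
  n <- length(t)
  th <- theta_deg * DEG2RAD
  # gravity direction in the sensor frame for a pure pitch rotation
  accel <- cbind(-sin(th), 0, cos(th))
  if (config$linear_accel) {
    w <- rate_dps * DEG2RAD
    alpha <- c(0, diff(w)) / c(1, diff(t))
    r <- config$seg_length_m
    accel[, 1] <- accel[, 1] - w^2 * r / 9.81
    accel[, 3] <- accel[, 3] - alpha * r / 9.81
  }
  gyro <- cbind(0, rate_dps, 0)
  if (config$accel_noise_sd > 0) {
    accel <- accel + matrix(stats::rnorm(3 * n, 0, config$accel_noise_sd),
                            n, 3)
  }
  if (config$gyro_noise_sd > 0) {
    gyro <- gyro + matrix(stats::rnorm(3 * n, 0, config$gyro_noise_sd),
                          n, 3)
  }
  accel <- sweep(sweep(accel, 2, config$accel_scale, "*"), 2,
                 config$accel_offset, "+")
  gyro <- sweep(gyro, 2, config$gyro_bias, "+")
  accel <- pmin(pmax(accel, -ACCEL_FULL_SCALE_G), ACCEL_FULL_SCALE_G)
  gyro <- pmin(pmax(gyro, -GYRO_FULL_SCALE_DPS), GYRO_FULL_SCALE_DPS)
  imu_stream(t, accel, gyro)
}

#' Six-position accelerometer calibration fixtures
#'
#' Generates the six static placement streams (+x, -x, +y, -y, +z, -z up)
#' with ideal readings of exactly +/-1 g on the gravity axis, corrupted by
#' the injected offset/scale errors and Gaussian noise. Feeding these to
#' [estimate_accel_calibration()] recovers the injected parameters (exactly
#' when noise-free).
#'
#' @param accel_offset 3-vector, g.
#' @param accel_scale 3-vector, dimensionless, positive.
#' @param noise_sd accelerometer noise SD in g, default 0.
#' @param n_samples samples per placement, default 260 (5 s at 52 Hz).
#' @param rate_hz sampling rate, default 52.
#' @param seed integer seed.
#' @return list of six [imu_stream()]s in the order +x, -x, +y, -y, +z, -z.
#' @export
six_position_fixtures <- function(accel_offset = c(0, 0, 0),
                                  accel_scale = c(1, 1, 1), noise_sd = 0,
                                  n_samples = 260, rate_hz = 52, seed = 1) {
  stopifnot(all(accel_scale > 0), noise_sd >= 0, n_samples >= 1)
  t <- (0:(n_samples - 1)) / rate_hz
  dirs <- list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
               c(0, 0, 1), c(0, 0, -1))
  with_seed(seed, function() {
    lapply(dirs, function(d) {
      ideal <- matrix(d, n_samples, 3, byrow = TRUE)
      if (noise_sd > 0) {
        ideal <- ideal + matrix(stats::rnorm(3 * n_samples, 0, noise_sd),
                                n_samples, 3)
      }
      meas <- sweep(sweep(ideal, 2, accel_scale, "*"), 2, accel_offset, "+")
      meas <- pmin(pmax(meas, -ACCEL_FULL_SCALE_G), ACCEL_FULL_SCALE_G)
      imu_stream(t, meas, matrix(0, n_samples, 3))
    })
  })
}
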