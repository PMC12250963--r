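#' End-to-end processing of a dual-IMU recording
#'
#' Applies calibration, runs the Madgwick filter on both units, and returns
#' the sagittal joint-angle series together with both units' Euler traces.
#' The distal unit's pitch trace is what gait event detection consumes when
#' the device is worn across the ankle (distal unit on the dorsum of the
#' foot).
#'
#' @param rec a [dual_imu_recording()].
#' @param proximal_params,distal_params [calibration_params()]; identity by
#'   default.
#' @param settings a [fusion_settings()].
#' @param distal_flip see [joint_angle()].
#' @return list with `angle` (a [joint_angle_series()]), `euler_proximal`,
#'   `euler_distal` (data frames `t, yaw, pitch, roll`) and `foot_pitch`
#'   (the distal pitch as an [angle_series()]).
#' @export
process_recording <- function(rec,
                              proximal_params = calibration_params(),
                              distal_params = calibration_params(),
                              settings = fusion_settings(),
                              distal_flip = FALSE) {
  stopifnot(inherits(rec, "dual_imu_recording"))
  cal <- apply_calibration(rec, proximal_params, distal_params)
  ep <- estimate_euler(cal$proximal, settings)
  ed <- estimate_euler(cal$distal, settings)
  ang <- joint_angle(ep, ed, joint = rec$joint, condition = rec$condition,
                     distal_flip = distal_flip)
  list(angle = ang,
       euler_proximal = ep,
       euler_distal = ed,
       foot_pitch = angle_series(ed$t, ed$pitch, source = "device"))
}
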