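#' Gait events from the foot-dorsum unit's sagittal orientation
#'
#' During walking the pitch of a unit on the dorsum of the foot shows one
#' prominent swing peak per gait cycle of that foot. Steps are counted as
#' those peaks, step time is the interval between consecutive peaks, and
#' toe-off is located at the pre-swing pitch minimum (the foot is maximally
#' plantarflexed as it leaves the ground). "Step" here means one cycle of
#' the instrumented foot.
#'
#' @name gait_events
NULL

#' Detect step peaks in a foot pitch trace
#'
#' Local maxima of the 4 Hz low-pass-filtered trace with topographic
#' prominence at least `min_prominence` and separation at least
#' `1 / max_cadence_hz`. Defaults are conservative for 3-5 km/h treadmill
#' walking (about 0.8-1.3 gait cycles per second per foot).
#'
#' @param foot_pitch an [angle_series()] of the foot-dorsum sagittal
#'   orientation, degrees.
#' @param min_prominence minimum peak prominence in degrees, default 10.
#' @param max_cadence_hz maximum credible cycle rate, default 3; peaks
#'   closer than `1 / max_cadence_hz` seconds are merged (more prominent
#'   wins).
#' @param cutoff_hz low-pass cutoff, default 4 Hz.
#' @return numeric vector of peak times in seconds (possibly empty).
#' @export
detect_steps <- function(foot_pitch, min_prominence = 10,
                         max_cadence_hz = 3, cutoff_hz = 4) {
  t <- foot_pitch$t
  if (length(t) < 2) return(numeric(0))
  dur <- t[length(t)] - t[1]
  if (dur < 1 / max_cadence_hz) {
    stop("insufficient data: series shorter than one minimum gait cycle")
  }
  rate <- rate_from_t(t)
  x <- lowpass(foot_pitch$angle, rate, cutoff_hz)
  idx <- find_peaks(x, min_prominence = min_prominence,
                    min_distance = max(1L, floor(rate / max_cadence_hz)))
  t[idx]
}

#' Step times from step peaks
#'
#' @param step_peak_t numeric vector of step peak times in seconds,
#'   strictly increasing.
#' @return consecutive differences in seconds; empty for fewer than two
#'   peaks.
#' @export
step_times <- function(step_peak_t) {
  if (length(step_peak_t) < 2) return(numeric(0))
  if (any(diff(step_peak_t) <= 0)) {
    stop("integrity error: step peak times not strictly increasing")
  }
  diff(step_peak_t)
}

#' Detect toe-off events
#'
#' For each step peak, toe-off is placed in the window from the previous
#' peak (or the series start, for the first peak) to the current peak:
#' either at the minimum of the filtered pitch (`rule = "min"`, default) or
#' at the last negative-to-positive zero crossing of the filtered pitch
#' rate preceding the peak (`rule = "gyro_zero"`). The device's published
#' protocol does not fix a toe-off criterion, so the rule is configuration.
#'
#' @param foot_pitch an [angle_series()] of foot-dorsum pitch, degrees.
#' @param step_peak_t step peak times from [detect_steps()].
#' @param rule `"min"` or `"gyro_zero"`.
#' @param cutoff_hz low-pass cutoff, default 4 Hz.
#' @return numeric vector of toe-off times, one per step peak, each
#'   strictly before its peak.
#' @export
detect_toe_off <- function(foot_pitch, step_peak_t,
                           rule = c("min", "gyro_zero"), cutoff_hz = 4) {
  rule <- match.arg(rule)
  if (length(step_peak_t) == 0) return(numeric(0))
  t <- foot_pitch$t
  rate <- rate_from_t(t)
  x <- lowpass(foot_pitch$angle, rate, cutoff_hz)
  peak_idx <- vapply(step_peak_t, function(tp) which.min(abs(t - tp)),
                     integer(1))
  prev_idx <- c(1L, peak_idx[-length(peak_idx)])
  vapply(seq_along(peak_idx), function(k) {
    lo <- prev_idx[k]; hi <- peak_idx[k]
    if (hi <= lo) return(t[lo])
    win <- lo:(hi - 1L)
    if (rule == "min") {
      t[win[which.min(x[win])]]
    } else {
      v <- diff(x[lo:hi]) * rate   # filtered pitch rate, deg/s
      up <- which(v[-1] > 0 & v[-length(v)] <= 0)
      if (length(up) == 0) t[win[which.min(x[win])]]
      else t[lo + up[length(up)]]
    }
  }, numeric(1))
}

#' Full gait-event extraction
#'
#' Runs [detect_steps()], [step_times()] and [detect_toe_off()] on a foot
#' pitch trace.
#'
#' @inheritParams detect_steps
#' @inheritParams detect_toe_off
#' @return an object of class `gait_events`: list with `step_peak_t`,
#'   `step_times`, `toe_off_t` (seconds) and integer `step_count`.
#' @export
extract_gait_events <- function(foot_pitch, min_prominence = 10,
                                max_cadence_hz = 3,
                                rule = c("min", "gyro_zero"),
                                cutoff_hz = 4) {
  rule <- match.arg(rule)
  peaks <- detect_steps(foot_pitch, min_prominence, max_cadence_hz, cutoff_hz)
  structure(list(step_peak_t = peaks,
                 step_times = step_times(peaks),
                 toe_off_t = detect_toe_off(foot_pitch, peaks, rule,
                                            cutoff_hz),
                 step_count = length(peaks)),
            class = "gait_events")
}

#' @export
print.gait_events <- function(x, ...) {
  cat(sprintf("<gait_events> %d steps", x$step_count))
  if (length(x$step_times) > 0) {
    cat(sprintf(", mean step time %.3f s", mean(x$step_times)))
  }
  cat(sprintf(", %d toe-off events\n", length(x$toe_off_t)))
  invisible(x)
}

#' Serialize gait events as JSON
#'
#' @param events a `gait_events` object.
#' @param path JSON output path.
#' @return `path`, invisibly.
#' @export
write_gait_events <- function(events, path) {
  jsonlite::write_json(
    list(step_peak_t = events$step_peak_t, step_times = events$step_times,
         toe_off_t = events$toe_off_t,
         step_count = jsonlite::unbox(as.integer(events$step_count))),
    path, digits = NA, auto_unbox = FALSE)
  invisible(path)
}
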