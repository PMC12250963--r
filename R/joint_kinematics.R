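#' Sagittal joint angle, flexion-extension cycles and range of motion
#'
#' With one unit on each segment of a hinge joint and the mounting
#' convention that flexion drives both pitches positive, the sagittal joint
#' angle is the algebraic sum of the two units' pitch angles. Cycles of a
#' flexion-extension exercise are segmented from the low-pass-filtered angle
#' trace and summarized as range of motion (ROM).
#'
#' @name joint_kinematics
NULL

#' Sagittal joint angle from two pitch traces
#'
#' `angle(t) = pitch_proximal(t) + pitch_distal(t)`. Units are mounted with
#' the y (pitch) axis mediolateral and polarities such that flexion
#' increases both pitches; if the distal unit was mounted with opposite
#' polarity set `distal_flip = TRUE` to subtract instead.
#'
#' @param proximal_euler,distal_euler data frames with columns `t` and
#'   `pitch` (degrees) on a shared timebase, as returned by
#'   [estimate_euler()].
#' @param joint `"knee"` or `"ankle"`.
#' @param condition `"bare"` or `"banded"`.
#' @param distal_flip negate the distal pitch before summing.
#' @return a [joint_angle_series()].
#' @export
joint_angle <- function(proximal_euler, distal_euler,
                        joint = c("knee", "ankle"),
                        condition = c("bare", "banded"),
                        distal_flip = FALSE) {
  joint <- match.arg(joint)
  condition <- match.arg(condition)
  if (nrow(proximal_euler) != nrow(distal_euler)) {
    stop("alignment error: pitch traces differ in length")
  }
  if (any(proximal_euler$t != distal_euler$t)) {
    stop("alignment error: pitch traces are not on a shared timebase")
  }
  sgn <- if (distal_flip) -1 else 1
  joint_angle_series(proximal_euler$t,
                     proximal_euler$pitch + sgn * distal_euler$pitch,
                     joint = joint, condition = condition)
}

#' Construct a joint-angle series
#'
#' @param t seconds, strictly increasing.
#' @param angle sagittal joint angle, degrees.
#' @param joint,condition recording annotations.
#' @return data frame of class `joint_angle_series` (also an
#'   [angle_series()]) with attributes `joint` and `condition`.
#' @export
joint_angle_series <- function(t, angle, joint = c("knee", "ankle"),
                               condition = c("bare", "banded")) {
  joint <- match.arg(joint)
  condition <- match.arg(condition)
  s <- angle_series(t, angle, source = "device")
  attr(s, "joint") <- joint
  attr(s, "condition") <- condition
  class(s) <- c("joint_angle_series", class(s))
  s
}

#' Segment flexion-extension cycles
#'
#' Low-pass filters the angle trace (zero-phase Butterworth, `cutoff_hz`),
#' finds the prominent maxima, and delimits each cycle by the local minima
#' on either side of a maximum (series endpoints act as boundaries for the
#' first and last cycle). The cycle baseline is the mean of its two
#' delimiting minima — robust to slow drift between repetitions — and
#' `rom = peak - baseline`. Cycles with `rom < min_rom` or duration below
#' `min_period_s` are discarded. Plateaued peaks resolve to their earliest
#' sample.
#'
#' @param series a [joint_angle_series()] or [angle_series()].
#' @param min_rom minimum excursion in degrees to keep a cycle, default 10.
#' @param min_period_s minimum cycle duration in seconds, default 0.5.
#' @param cutoff_hz low-pass cutoff, default 4 Hz.
#' @return data frame of class `flex_ext_cycles` with columns
#'   `start_t, peak_t, end_t, peak_angle, rom`; zero rows when no cycle
#'   qualifies.
#' @export
segment_flexion_extension <- function(series, min_rom = 10,
                                      min_period_s = 0.5, cutoff_hz = 4) {
  if (nrow(series) == 0) stop("insufficient data: empty angle series")
  t <- series$t
  if (nrow(series) < 3) return(empty_cycles())
  rate <- rate_from_t(t)
  x <- lowpass(series$angle, rate, cutoff_hz)
  min_dist <- max(1L, floor(min_period_s * rate))
  peaks <- find_peaks(x, min_prominence = min_rom, min_distance = min_dist)
  if (length(peaks) == 0) return(empty_cycles())

  # cycle boundaries: minimum of the filtered trace between adjacent peaks,
  # and the series endpoints outside the first/last peak
  bounds <- integer(length(peaks) + 1)
  bounds[1] <- which.min(x[1:peaks[1]])
  if (length(peaks) > 1) {
    for (k in seq_len(length(peaks) - 1)) {
      seg <- peaks[k]:peaks[k + 1]
      bounds[k + 1] <- seg[which.min(x[seg])]
    }
  }
  seg <- peaks[length(peaks)]:length(x)
  bounds[length(bounds)] <- seg[which.min(x[seg])]

  cyc <- data.frame(start_t = t[bounds[-length(bounds)]],
                    peak_t = t[peaks],
                    end_t = t[bounds[-1]],
                    peak_angle = x[peaks],
                    rom = x[peaks] -
                      (x[bounds[-length(bounds)]] + x[bounds[-1]]) / 2)
  keep <- cyc$rom >= min_rom & (cyc$end_t - cyc$start_t) >= min_period_s &
    cyc$start_t < cyc$peak_t & cyc$peak_t < cyc$end_t
  cyc <- cyc[keep, , drop = FALSE]
  rownames(cyc) <- NULL
  class(cyc) <- c("flex_ext_cycles", "data.frame")
  cyc
}

empty_cycles <- function() {
  cyc <- data.frame(start_t = numeric(0), peak_t = numeric(0),
                    end_t = numeric(0), peak_angle = numeric(0),
                    rom = numeric(0))
  class(cyc) <- c("flex_ext_cycles", "data.frame")
  cyc
}

#' Summarize range of motion over segmented cycles
#'
#' @param cycles a `flex_ext_cycles` data frame from
#'   [segment_flexion_extension()].
#' @return an object of class `rom_summary`: list with `max_rom`, `mean_rom`
#'   (degrees), `n_cycles`, and `empty` flag. An empty input yields an
#'   explicit empty summary (`empty = TRUE`, ROM fields `NA`), not zeros and
#'   not an error.
#' @export
rom_summary <- function(cycles) {
  if (nrow(cycles) == 0) {
    out <- list(max_rom = NA_real_, mean_rom = NA_real_, n_cycles = 0L,
                empty = TRUE)
  } else {
    out <- list(max_rom = max(cycles$rom), mean_rom = mean(cycles$rom),
                n_cycles = nrow(cycles), empty = FALSE)
  }
  structure(out, class = "rom_summary")
}

#' @export
print.rom_summary <- function(x, ...) {
  if (x$empty) {
    cat("<rom_summary> no qualifying cycles\n")
  } else {
    cat(sprintf("<rom_summary> %d cycles: max ROM %.1f deg, mean ROM %.1f deg\n",
                x$n_cycles, x$max_rom, x$mean_rom))
  }
  invisible(x)
}
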