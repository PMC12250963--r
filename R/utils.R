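# Shared signal helpers: zero-phase low-pass filtering and prominence-gated
# peak detection. Both cycle segmentation and gait event detection filter at
# the same 4 Hz cutoff so the two modules see consistent traces.

# sampling rate implied by a timestamp vector (median interval)
rate_from_t <- function(t) {
  if (length(t) < 2) stop("insufficient data: need at least 2 samples")
  1 / stats::median(diff(t))
}

#' Zero-phase Butterworth low-pass filter
#'
#' Second-order Butterworth applied forward and backward
#' (zero phase lag, so peak times are not shifted). When the cutoff is at or
#' above the Nyquist frequency the input is returned unchanged.
#'
#' @param x numeric signal.
#' @param rate_hz sampling rate of `x`.
#' @param cutoff_hz cutoff frequency, default 4 Hz (voluntary limb motion
#'   and walking stay below ~2 Hz per foot, so 4 Hz keeps the kinematics and
#'   strips fusion jitter).
#' @return filtered signal, same length as `x`.
#' @export
lowpass <- function(x, rate_hz, cutoff_hz = 4) {
  n <- length(x)
  if (n < 12 || cutoff_hz >= rate_hz / 2) return(x)
  bf <- signal::butter(2, cutoff_hz / (rate_hz / 2), type = "low")
  # odd-reflection padding to suppress filtfilt edge transients
  p <- min(n - 1, max(9, ceiling(3 * rate_hz / cutoff_hz)))
  ext <- c(2 * x[1] - x[(p + 1):2], x, 2 * x[n] - x[(n - 1):(n - p)])
  y <- as.numeric(signal::filtfilt(bf, ext))
  y[(p + 1):(p + n)]
}

#' Prominence-gated local maxima
#'
#' Finds strict local maxima of a signal, computes each peak's topographic
#' prominence (height above the highest saddle separating it from a higher
#' peak, with the signal minimum as the reference for the global maximum),
#' drops peaks below `min_prominence`, and enforces a minimum index
#' separation keeping the more prominent peak of any conflicting pair.
#' Plateaus resolve to their earliest sample.
#'
#' @param x numeric signal.
#' @param min_prominence minimum prominence to keep a peak (same units as
#'   `x`).
#' @param min_distance minimum separation between kept peaks, in samples.
#' @return integer vector of peak indices, increasing.
#' @export
find_peaks <- function(x, min_prominence = 0, min_distance = 1) {
  n <- length(x)
  if (n < 3) return(integer(0))
  # strict rise before, fall-or-end after; plateaus take the first sample
  cand <- integer(0)
  i <- 2
  while (i <= n) {
    if (x[i] > x[i - 1]) {
      j <- i
      while (j < n && x[j + 1] == x[j]) j <- j + 1
      if (j == n || x[j + 1] < x[j]) cand <- c(cand, i)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(cand) == 0) return(integer(0))
  prom <- vapply(cand, function(p) peak_prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  cand <- cand[keep]; prom <- prom[keep]
  if (length(cand) <= 1 || min_distance <= 1) return(cand)
  # greedy by prominence, enforcing separation
  ord <- order(-prom, cand)
  chosen <- integer(0)
  for (k in ord) {
    if (all(abs(cand[k] - chosen) >= min_distance)) chosen <- c(chosen, cand[k])
  }
  sort(chosen)
}

# topographic prominence of the peak at index p
peak_prominence <- function(x, p) {
  n <- length(x)
  h <- x[p]
  # walk left until a strictly higher sample; track the minimum en route
  left_min <- h
  i <- p - 1
  while (i >= 1 && x[i] <= h) {
    if (x[i] < left_min) left_min <- x[i]
    i <- i - 1
  }
  if (i < 1) left_min <- min(x[1:p])
  right_min <- h
  i <- p + 1
  while (i <= n && x[i] <= h) {
    if (x[i] < right_min) right_min <- x[i]
    i <- i + 1
  }
  if (i > n) right_min <- min(x[p:n])
  h - max(left_min, right_min)
}

# run fn with a private RNG stream seeded by `seed`, restoring global state
with_seed <- function(seed, fn) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}
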