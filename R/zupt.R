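# Foot-flat (zero-velocity) detection: thresholded energy detector on gyro
# magnitude and accelerometer deviation from 1 g over a short sliding window.

#' Foot-flat detector settings
#'
#' A sample counts as still when the gyroscope magnitude is below
#' `gyro_thresh` and the accelerometer magnitude is within `accel_thresh` of
#' gravity, and every sample in a centred window of `window_s` seconds agrees.
#' Runs shorter than `min_duration_s` are discarded; runs separated by less
#' than `merge_gap_s` are merged.
#'
#' @param gyro_thresh Gyro magnitude threshold, rad/s (default 0.5).
#' @param accel_thresh | |accel| - g | threshold, m/s^2 (default 0.5).
#' @param window_s Sliding window length, s (default 0.05).
#' @param min_duration_s Minimum stationary duration, s (default 0.05).
#' @param merge_gap_s Gaps shorter than this are merged, s (default 0.05).
#' @param g Gravity magnitude, m/s^2.
#' @return A `zupt_params` list.
#' @export
zupt_params <- function(gyro_thresh = 0.5, accel_thresh = 0.5,
                        window_s = 0.05, min_duration_s = 0.05,
                        merge_gap_s = 0.05, g = STANDARD_GRAVITY) {
  stopifnot(gyro_thresh > 0, accel_thresh > 0, window_s >= 0,
            min_duration_s >= 0, merge_gap_s >= 0, g > 0)
  structure(
    list(gyro_thresh = gyro_thresh, accel_thresh = accel_thresh,
         window_s = window_s, min_duration_s = min_duration_s,
         merge_gap_s = merge_gap_s, g = g),
    class = "zupt_params"
  )
}

#' Construct a foot-flat sequence
#'
#' Ordered, disjoint stationary (foot-flat) intervals of one recording, each
#' with a representative time `t_rep` at which the foot position is read for
#' chord distances.
#'
#' @param start_index,end_index Integer sample indices (closed intervals).
#' @param t_rep Representative times, seconds, one per interval.
#' @return A `foot_flat_sequence` with fields `intervals` (data.frame
#'   `start_index`, `end_index`, `t_rep`) and `n` (interval count).
#' @export
foot_flat_sequence <- function(start_index = integer(), end_index = integer(),
                               t_rep = numeric()) {
  start_index <- as.integer(start_index)
  end_index <- as.integer(end_index)
  stopifnot(length(start_index) == length(end_index),
            length(t_rep) == length(start_index))
  if (length(start_index)) {
    if (any(start_index > end_index)) stopf("start_index > end_index")
    if (any(diff(start_index) <= 0) && length(start_index) > 1L) {
      stopf("intervals must be time-ordered")
    }
    if (length(start_index) > 1L &&
        any(start_index[-1L] <= end_index[-length(end_index)])) {
      stopf("intervals must be disjoint")
    }
  }
  structure(
    list(
      intervals = data.frame(start_index = start_index,
                             end_index = end_index, t_rep = t_rep),
      n = length(start_index)
    ),
    class = "foot_flat_sequence"
  )
}

#' @export
print.foot_flat_sequence <- function(x, ...) {
  cat(sprintf("<foot_flat_sequence> %d foot-flat interval(s)\n", x$n))
  invisible(x)
}

#' Detect foot-flat (zero-velocity) periods
#'
#' Finds the intervals during which the foot is flat on the ground and the
#' sensor velocity is known to be zero, by thresholding the raw gyroscope and
#' accelerometer magnitudes (no orientation estimate needed).  Each interval's
#' representative time `t_rep` is its midpoint sample time.
#'
#' @param rec A uniformly sampled `imu_recording`.
#' @param params A [zupt_params()] object.
#' @return A [foot_flat_sequence()].
#' @export
detect_foot_flat <- function(rec, params = zupt_params()) {
  validate_recording(rec)
  t <- rec$timestamps
  n <- length(t)
  fs <- rec$meta$sample_rate_hz
  win <- max(1L, round(params$window_s * fs))
  if (n < win) stopf("recording shorter than the detector window")

  gmag <- sqrt(rowSums(rec$gyro^2))
  adev <- abs(sqrt(rowSums(rec$accel^2)) - params$g)
  still <- (gmag < params$gyro_thresh) & (adev < params$accel_thresh)

  # erosion: sample i is stationary iff all samples in its centred window are
  if (win > 1L) {
    h <- win %/% 2L
    cs <- cumsum(c(0L, as.integer(still)))
    lo <- pmax(1L, seq_len(n) - h)
    hi <- pmin(n, seq_len(n) + h)
    still <- (cs[hi + 1L] - cs[lo]) == (hi - lo + 1L)
  }

  r <- rle(still)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  s <- starts[r$values]
  e <- ends[r$values]
  if (length(s) > 1L) {
    # merge runs separated by short gaps
    gap <- t[s[-1L]] - t[e[-length(e)]]
    brk <- which(gap >= params$merge_gap_s)
    s <- s[c(1L, brk + 1L)]
    e <- e[c(brk, length(e))]
  }
  if (length(s)) {
    dur <- t[e] - t[s]
    ok <- dur >= params$min_duration_s
    s <- s[ok]; e <- e[ok]
  }
  t_rep <- (t[s] + t[e]) / 2
  foot_flat_sequence(s, e, t_rep)
}

#' Per-sample stationary mask from a foot-flat sequence
#'
#' @param flats A `foot_flat_sequence`.
#' @param n Total number of samples.
#' @return Logical vector of length `n`, `TRUE` inside any interval.
#' @export
stationary_mask <- function(flats, n) {
  mask <- logical(n)
  iv <- flats$intervals
  for (i in seq_len(nrow(iv))) {
    mask[iv$start_index[i]:iv$end_index[i]] <- TRUE
  }
  mask
}

#' Mean gyroscope over stationary samples (bias estimate)
#'
#' The gyroscope should read zero whenever the foot is flat and still; the
#' mean over all detected stationary samples estimates the constant gyro bias
#' and is subtracted before orientation propagation.
#'
#' @param rec An `imu_recording`.
#' @param flats A `foot_flat_sequence` for `rec`.
#' @return Length-3 numeric bias (rad/s); zeros if no intervals.
#' @export
estimate_gyro_bias <- function(rec, flats) {
  if (flats$n == 0L) return(c(0, 0, 0))
  mask <- stationary_mask(flats, n_samples(rec))
  colMeans(rec$gyro[mask, , drop = FALSE])
}
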