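# Strapdown trajectory reconstruction: trapezoidal integration of Earth-frame
# free acceleration with zero-velocity updates (linear velocity de-drifting
# between consecutive stationary intervals).

#' Construct a foot trajectory object
#'
#' @param timestamps Sample times, s.
#' @param position N x 3 matrix, metres, Earth frame (z vertical).
#' @param velocity N x 3 matrix, m/s.
#' @param zupt_applied Logical: were zero-velocity updates applied?
#' @return A `foot_trajectory`.
#' @export
foot_trajectory <- function(timestamps, position, velocity,
                            zupt_applied = TRUE) {
  position <- as.matrix(position)
  velocity <- as.matrix(velocity)
  stopifnot(nrow(position) == length(timestamps),
            nrow(velocity) == length(timestamps),
            ncol(position) == 3L, ncol(velocity) == 3L)
  structure(
    list(timestamps = as.numeric(timestamps), position = position,
         velocity = velocity, zupt_applied = zupt_applied),
    class = "foot_trajectory"
  )
}

#' @export
print.foot_trajectory <- function(x, ...) {
  n <- length(x$timestamps)
  cat(sprintf("<foot_trajectory> %d samples over %.3f s (ZUPT %s)\n",
              n, x$timestamps[n] - x$timestamps[1L],
              if (isTRUE(x$zupt_applied)) "applied" else "not applied"))
  invisible(x)
}

#' Integrate free acceleration to a ZUPT-corrected foot trajectory
#'
#' Velocity is obtained by trapezoidal integration of the Earth-frame free
#' acceleration.  Inside every stationary interval the velocity is pinned to
#' zero.  Between consecutive stationary intervals the velocity is integrated
#' from zero and a linear-in-time ramp is subtracted so that it returns to
#' zero at the next interval (classic linear de-drifting); position then
#' follows by integrating the corrected velocity, with the origin at the
#' first sample.  Samples before the first and after the last stationary
#' interval are integrated one-sidedly and should be excluded from distance
#' computations (which [stride_distances()] does by construction).
#'
#' @param free_acc A `free_acceleration` (see [free_acceleration()]).
#' @param flats The `foot_flat_sequence` detected on the same recording.
#' @return A [foot_trajectory()].  With an empty `flats` the uncorrected
#'   double integral is returned with a warning (drift unbounded).
#' @export
integrate_trajectory <- function(free_acc, flats) {
  t <- free_acc$timestamps
  n <- length(t)
  acc <- free_acc$accel
  dt <- 1 / free_acc$sample_rate_hz
  V <- matrix(0, n, 3L)

  if (flats$n == 0L) {
    warnf("no stationary intervals: returning uncorrected dead-reckoning (drift unbounded)")
    V <- cumtrapz_uniform(dt, acc)
    P <- cumtrapz_uniform(dt, V)
    return(foot_trajectory(t, P, V, zupt_applied = FALSE))
  }

  iv <- flats$intervals
  m <- nrow(iv)

  # lead-in: integrate backward from zero velocity at the first stance
  s1 <- iv$start_index[1L]
  if (s1 > 1L) {
    idx <- 1L:s1
    vseg <- cumtrapz_uniform(dt, acc[idx, , drop = FALSE])
    V[idx, ] <- sweep(vseg, 2L, vseg[length(idx), ])
  }
  # segments between consecutive stationary intervals: linear de-drift
  if (m > 1L) {
    for (k in seq_len(m - 1L)) {
      a <- iv$end_index[k]
      b <- iv$start_index[k + 1L]
      idx <- a:b
      vseg <- cumtrapz_uniform(dt, acc[idx, , drop = FALSE])
      drift <- vseg[length(idx), ]
      lam <- (t[idx] - t[a]) / (t[b] - t[a])
      V[idx, ] <- vseg - outer(lam, drift)
    }
  }
  # tail: integrate forward from zero velocity at the last stance
  eM <- iv$end_index[m]
  if (eM < n) {
    idx <- eM:n
    V[idx, ] <- cumtrapz_uniform(dt, acc[idx, , drop = FALSE])
  }
  # pin stance velocity to zero exactly
  for (k in seq_len(m)) V[iv$start_index[k]:iv$end_index[k], ] <- 0

  P <- cumtrapz_uniform(dt, V)
  foot_trajectory(t, P, V, zupt_applied = TRUE)
}
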