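# Orientation estimation: gated complementary (Mahony-style) filter fusing
# gyroscope propagation with the accelerometer's gravity direction, and
# Earth-frame gravity-free acceleration.

#' Standard gravity used throughout the package (m/s^2)
#' @export
STANDARD_GRAVITY <- 9.80665

#' Orientation filter settings
#'
#' @param kp Proportional gain (1/s) pulling the estimated gravity direction
#'   toward the measured accelerometer direction.  Larger values trust the
#'   accelerometer more; the default 2 gives a ~0.5 s tilt time constant.
#' @param gate Two-element vector: the accelerometer correction is applied
#'   only when `|accel|` lies within `gate * g` (default 0.9--1.1 g), i.e.
#'   when the accelerometer plausibly measures gravity alone.
#' @param gyro_gate Additional quasi-static condition: the correction is
#'   applied only while the gyro magnitude is below this value (rad/s,
#'   default 0.3).  During swing the foot rotates fast while `|accel|` can
#'   still sweep through 1 g, which would otherwise pull the tilt estimate
#'   toward a non-gravitational acceleration.
#' @param init_window_s Initial quasi-static window (s) whose mean
#'   accelerometer vector fixes the initial tilt; initial yaw is 0.
#' @param g Gravity magnitude, m/s^2.
#' @return An `orientation_params` list.
#' @export
orientation_params <- function(kp = 2, gate = c(0.9, 1.1), gyro_gate = 0.3,
                               init_window_s = 0.25, g = STANDARD_GRAVITY) {
  stopifnot(kp >= 0, length(gate) == 2L, gate[1L] < gate[2L], gyro_gate > 0,
            init_window_s >= 0, g > 0)
  structure(list(kp = kp, gate = gate, gyro_gate = gyro_gate,
                 init_window_s = init_window_s, g = g),
            class = "orientation_params")
}

#' Estimate per-sample body-to-Earth orientation
#'
#' Propagates a unit quaternion with the (bias-corrected) gyroscope and
#' applies a proportional tilt correction toward the measured gravity
#' direction whenever the accelerometer magnitude is close to 1 g.  Yaw is
#' unobservable without a magnetometer and is initialized to zero; all
#' downstream distance quantities are invariant to a global yaw offset.
#'
#' @param rec A uniformly sampled `imu_recording` (see [is_uniform()]).
#' @param params An [orientation_params()] object.
#' @param gyro_bias Length-3 gyroscope bias (rad/s) subtracted before
#'   propagation; typically estimated from detected stationary intervals.
#' @return An `orientation_track`: list with `timestamps` and `quaternions`
#'   (N x 4, Hamilton scalar-first, body -> Earth; Earth z up).
#' @export
estimate_orientation <- function(rec, params = orientation_params(),
                                 gyro_bias = c(0, 0, 0)) {
  validate_recording(rec)
  if (!is_uniform(rec)) {
    stopf("recording is not uniformly sampled; resample_uniform() first")
  }
  t <- rec$timestamps
  n <- length(t)
  dt <- 1 / rec$meta$sample_rate_hz
  acc <- rec$accel
  gyr <- sweep(rec$gyro, 2L, gyro_bias)
  g <- params$g
  lo <- params$gate[1L] * g
  hi <- params$gate[2L] * g
  kp <- params$kp

  # initial tilt from the mean accelerometer over the init window
  iw <- max(1L, min(n, ceiling(params$init_window_s / dt)))
  a0 <- colMeans(acc[seq_len(iw), , drop = FALSE])
  if (sqrt(sum(a0^2)) < 1e-6) a0 <- c(0, 0, 1)
  q <- quat_from_two_vectors(a0, c(0, 0, 1))

  anorm <- sqrt(rowSums(acc^2))
  gnorm <- sqrt(rowSums(gyr^2))
  ggate <- params$gyro_gate
  Q <- matrix(0, n, 4L)
  Q[1L, ] <- q
  w <- q[1L]; x <- q[2L]; y <- q[3L]; z <- q[4L]
  for (k in seq_len(n - 1L)) {
    # midpoint angular rate over the propagation interval
    wx <- (gyr[k, 1L] + gyr[k + 1L, 1L]) / 2
    wy <- (gyr[k, 2L] + gyr[k + 1L, 2L]) / 2
    wz <- (gyr[k, 3L] + gyr[k + 1L, 3L]) / 2
    an <- anorm[k]
    if (kp > 0 && an > lo && an < hi && gnorm[k] < ggate) {
      # measured and predicted gravity directions in the body frame
      ax <- acc[k, 1L] / an; ay <- acc[k, 2L] / an; az <- acc[k, 3L] / an
      vx <- 2 * (x * z - w * y)
      vy <- 2 * (y * z + w * x)
      vz <- 1 - 2 * (x * x + y * y)
      wx <- wx + kp * (ay * vz - az * vy)
      wy <- wy + kp * (az * vx - ax * vz)
      wz <- wz + kp * (ax * vy - ay * vx)
    }
    ang <- sqrt(wx * wx + wy * wy + wz * wz) * dt
    if (ang > 1e-12) {
      h <- ang / 2
      s <- sin(h) / (ang / dt)
      dw <- cos(h); dx <- wx * s; dy <- wy * s; dz <- wz * s
      nw <- w * dw - x * dx - y * dy - z * dz
      nx <- w * dx + x * dw + y * dz - z * dy
      ny <- w * dy - x * dz + y * dw + z * dx
      nz <- w * dz + x * dy - y * dx + z * dw
      nn <- sqrt(nw * nw + nx * nx + ny * ny + nz * nz)
      w <- nw / nn; x <- nx / nn; y <- ny / nn; z <- nz / nn
    }
    Q[k + 1L, 1L] <- w; Q[k + 1L, 2L] <- x
    Q[k + 1L, 3L] <- y; Q[k + 1L, 4L] <- z
  }
  structure(list(timestamps = t, quaternions = Q),
            class = "orientation_track")
}

#' @export
print.orientation_track <- function(x, ...) {
  cat(sprintf("<orientation_track> %d samples over %.3f s\n",
              length(x$timestamps),
              x$timestamps[length(x$timestamps)] - x$timestamps[1L]))
  invisible(x)
}

#' Tilt of each orientation sample relative to vertical
#'
#' Angle (rad) between the body z axis expressed in the Earth frame and the
#' Earth vertical; 0 for a level sensor.  Mainly a diagnostic.
#'
#' @param track An `orientation_track`.
#' @return Numeric vector of tilt angles, rad.
#' @export
tilt_angle <- function(track) {
  Q <- track$quaternions
  # Earth-frame z component of the rotated body z axis
  cz <- 1 - 2 * (Q[, 2L]^2 + Q[, 3L]^2)
  acos(pmin(1, pmax(-1, cz)))
}

#' Earth-frame gravity-free acceleration
#'
#' Rotates each body-frame accelerometer sample into the Earth frame using
#' the estimated orientation and subtracts standard gravity from the vertical
#' component: `a_earth[i] = R(q_i) a_body[i] - (0, 0, g)`.
#'
#' @param rec The source `imu_recording`.
#' @param track The matching `orientation_track`.
#' @param g Gravity magnitude to subtract, m/s^2.
#' @return A `free_acceleration`: list with `timestamps`, `accel` (N x 3,
#'   Earth frame, z up) and `sample_rate_hz`.
#' @export
free_acceleration <- function(rec, track, g = STANDARD_GRAVITY) {
  validate_recording(rec)
  if (length(track$timestamps) != length(rec$timestamps)) {
    stopf("orientation track (%d) and recording (%d) lengths differ",
          length(track$timestamps), length(rec$timestamps))
  }
  ae <- quat_rotate_rows(track$quaternions, rec$accel)
  ae[, 3L] <- ae[, 3L] - g
  structure(
    list(timestamps = rec$timestamps, accel = ae,
         sample_rate_hz = rec$meta$sample_rate_hz),
    class = "free_acceleration"
  )
}
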