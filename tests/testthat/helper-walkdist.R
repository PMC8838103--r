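# Shared fixture builders and independent numerical oracles.

g_std <- walkdist::STANDARD_GRAVITY

# A recording with constant body-frame signals plus optional white noise.
constant_recording <- function(dur = 5, fs = 128,
                               accel = c(0, 0, g_std), gyro = c(0, 0, 0),
                               accel_sd = 0, gyro_sd = 0, foot = "right") {
  n <- round(dur * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  acc <- matrix(accel, n, 3L, byrow = TRUE)
  gyr <- matrix(gyro, n, 3L, byrow = TRUE)
  if (accel_sd > 0) acc <- acc + matrix(rnorm(3L * n, 0, accel_sd), n, 3L)
  if (gyro_sd > 0) gyr <- gyr + matrix(rnorm(3L * n, 0, gyro_sd), n, 3L)
  imu_recording(t, acc, gyr,
                sensor_meta(sample_rate_hz = fs, foot_side = foot))
}

# Cumulative Simpson integration (independent oracle; exact for cubics).
# Values are only defined at odd indices 1, 3, 5, ...; even indices are NA.
cum_simpson <- function(dt, y) {
  n <- length(y)
  out <- rep(NA_real_, n)
  out[1L] <- 0
  ks <- seq(3L, n, by = 2L)
  for (k in ks) {
    out[k] <- out[k - 2L] + dt / 3 * (y[k - 2L] + 4 * y[k - 1L] + y[k])
  }
  out
}

# Jaccard overlap of two closed index intervals.
interval_jaccard <- function(a0, a1, b0, b1) {
  inter <- max(0, min(a1, b1) - max(a0, b0) + 1)
  union <- (a1 - a0 + 1) + (b1 - b0 + 1) - inter
  inter / union
}

# Yaw angle (rotation about Earth z) of a scalar-first quaternion row.
quat_yaw <- function(q) {
  atan2(2 * (q[1L] * q[4L] + q[2L] * q[3L]),
        1 - 2 * (q[3L]^2 + q[4L]^2))
}

# Small noise-free walk reused by several files: one pass, 10 strides.
ten_stride_sim <- function(noise = noise_model(0, 0)) {
  simulate_walk(
    gait_protocol(walkway_length = 13, mode = "fixed_distance", target = 13,
                  stride_length = 1.3),
    noise
  )
}
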