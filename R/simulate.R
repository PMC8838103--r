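# Forward gait simulator with an inverse sensor model.
#
# Foot motion is built as alternating stance dwells (position and attitude
# constant, velocity exactly zero) and smooth swings: minimum-jerk horizontal
# displacement, a sin^3 vertical lift and a sin^3 sagittal pitch bump, all
# with continuous position, velocity and acceleration.  Body-frame signals
# follow from the exact inverse sensor equations
#   accel_body = R(q)^T (a_earth + (0,0,g)),   gyro_body from the attitude
# rates, with optional additive Gaussian noise and constant biases.  Every
# simulated walk carries its ground truth: per-foot stance schedule, true
# chord distances, true trajectory and attitude.

#' Walking-test protocol for the gait simulator
#'
#' Describes back-and-forth walking on a straight walkway with turns at each
#' end, either over a fixed total straight-line distance (e.g. a 400 m walk:
#' 20 m walkway, 20 lengths) or over a fixed time (e.g. a 6-minute walk).
#'
#' @param walkway_length Walkway length between the turn points, metres.
#' @param mode `"fixed_distance"` (target metres of straight walking) or
#'   `"fixed_time"` (target seconds).
#' @param target Target distance (m) or duration (s) depending on `mode`.
#' @param stride_length Nominal stride length, metres (rounded so that an
#'   integer number of strides spans the walkway).
#' @param cadence Strides per second per foot (default 0.9, a fast walk).
#' @param stance_fraction Fraction of the gait cycle the foot is flat and
#'   still (default 0.35).
#' @param turn_style `"pivot"` (heading change on the spot during an extended
#'   stance) or `"arc"` (3--5 short strides along a semicircular cap).
#' @param turn_radius Semicircle radius for arc turns, metres.
#' @param turn_duration Pivot rotation time, seconds.
#' @param n_turn_steps Number of short strides in an arc turn.
#' @param step_height Vertical swing apex, metres.
#' @param pitch_amp Sagittal foot-pitch amplitude during swing, rad.
#' @param lateral_offset Lateral distance of each foot from the walkway
#'   midline, metres.
#' @param lead_in_s Initial still standing time, seconds (lets the
#'   orientation filter settle).
#' @param tail_s Final still standing time, seconds.
#' @return A `gait_protocol` object.
#' @export
gait_protocol <- function(walkway_length = 20,
                          mode = c("fixed_distance", "fixed_time"),
                          target = 400,
                          stride_length = 1.3,
                          cadence = 0.9,
                          stance_fraction = 0.35,
                          turn_style = c("pivot", "arc"),
                          turn_radius = 0.5,
                          turn_duration = 1.2,
                          n_turn_steps = 4,
                          step_height = 0.05,
                          pitch_amp = 0.35,
                          lateral_offset = 0.06,
                          lead_in_s = 1.5,
                          tail_s = 1.0) {
  mode <- match.arg(mode)
  turn_style <- match.arg(turn_style)
  if (walkway_length < 5) stopf("walkway_length must be >= 5 m")
  if (stride_length <= 0.3 || stride_length >= 2.5) {
    stopf("stride_length must lie in (0.3, 2.5) m")
  }
  if (stance_fraction <= 0.2 || stance_fraction >= 0.8) {
    stopf("stance_fraction must lie in (0.2, 0.8)")
  }
  if (stride_length > walkway_length) {
    stopf("stride length exceeds the walkway")
  }
  if (cadence <= 0 || target <= 0 || turn_radius <= 0) {
    stopf("cadence, target and turn_radius must be positive")
  }
  if (turn_style == "arc" && turn_radius <= lateral_offset) {
    stopf("turn_radius must exceed the lateral foot offset")
  }
  n_turn_steps <- as.integer(n_turn_steps)
  if (n_turn_steps < 3L || n_turn_steps > 5L) {
    stopf("n_turn_steps must be 3, 4 or 5")
  }
  structure(
    list(walkway_length = walkway_length, mode = mode, target = target,
         stride_length = stride_length, cadence = cadence,
         stance_fraction = stance_fraction, turn_style = turn_style,
         turn_radius = turn_radius, turn_duration = turn_duration,
         n_turn_steps = n_turn_steps, step_height = step_height,
         pitch_amp = pitch_amp, lateral_offset = lateral_offset,
         lead_in_s = lead_in_s, tail_s = tail_s),
    class = "gait_protocol"
  )
}

#' Sensor noise and bias model for the simulator
#'
#' @param accel_sd Accelerometer white-noise SD, m/s^2 (default 0.05).
#' @param gyro_sd Gyroscope white-noise SD, rad/s (default 0.005).
#' @param accel_bias Length-3 constant accelerometer bias, m/s^2.
#' @param gyro_bias Length-3 constant gyroscope bias, rad/s.
#' @param seed Integer seed; identical seed and parameters give
#'   bit-identical recordings.  `NULL` draws from the session RNG.
#' @return A `noise_model` object.
#' @export
noise_model <- function(accel_sd = 0.05, gyro_sd = 0.005,
                        accel_bias = c(0, 0, 0), gyro_bias = c(0, 0, 0),
                        seed = NULL) {
  stopifnot(accel_sd >= 0, gyro_sd >= 0,
            length(accel_bias) == 3L, length(gyro_bias) == 3L)
  structure(
    list(accel_sd = accel_sd, gyro_sd = gyro_sd,
         accel_bias = as.numeric(accel_bias),
         gyro_bias = as.numeric(gyro_bias), seed = seed),
    class = "noise_model"
  )
}

# --- phase schedule -------------------------------------------------------

new_phase <- function(type, t0, t1, x0, y0, x1, y1, yaw0, yaw1,
                      apex = 0, pitch_amp = 0, segment = "straight") {
  list(type = type, t0 = t0, t1 = t1, x0 = x0, y0 = y0, x1 = x1, y1 = y1,
       yaw0 = yaw0, yaw1 = yaw1, apex = apex, pitch_amp = pitch_amp,
       segment = segment)
}

# Build the phase list for one foot.  `lat` is the signed lateral offset of
# this foot from the walkway midline (+ = left of initial travel direction).
build_foot_phases <- function(p, lat, extra_lead) {
  T_cyc <- 1 / p$cadence
  T_st <- p$stance_fraction * T_cyc
  T_sw <- T_cyc - T_st
  n_str <- max(1L, round(p$walkway_length / p$stride_length))
  s_eff <- p$walkway_length / n_str

  arc <- p$turn_style == "arc"
  if (arc) {
    r <- p$turn_radius
    R_f <- r + lat          # outer foot has the larger cap radius
    y_out <- r - R_f        # = -lat
    y_back <- r + R_f
  } else {
    y_out <- lat
    y_back <- lat
  }

  passes <- if (p$mode == "fixed_distance") {
    max(1L, round(p$target / p$walkway_length))
  } else {
    ceiling(p$target / (n_str * T_cyc)) + 3L
  }

  phases <- vector("list", 0L)
  add <- function(ph) phases[[length(phases) + 1L]] <<- ph
  add_dwell <- function(t0, dur, x, y, yaw, segment) {
    np <- length(phases)
    if (np > 0L && phases[[np]]$type == "dwell" &&
        phases[[np]]$x1 == x && phases[[np]]$y1 == y &&
        phases[[np]]$yaw1 == yaw) {
      phases[[np]]$t1 <<- phases[[np]]$t1 + dur
    } else {
      add(new_phase("dwell", t0, t0 + dur, x, y, x, y, yaw, yaw,
                    segment = segment))
    }
  }

  t <- 0
  x <- 0; y <- y_out; yaw <- 0; dir <- 1
  add_dwell(t, p$lead_in_s + extra_lead, x, y, yaw, "straight")
  t <- p$lead_in_s + extra_lead

  end_time <- if (p$mode == "fixed_time") p$target else Inf

  for (pass in seq_len(passes)) {
    going_out <- dir > 0
    for (j in seq_len(n_str)) {
      if (t > end_time) break
      x2 <- x + dir * s_eff
      add(new_phase("swing", t, t + T_sw, x, y, x2, y, yaw, yaw,
                    apex = p$step_height, pitch_amp = p$pitch_amp))
      t <- t + T_sw
      add_dwell(t, T_st, x2, y, yaw, "straight")
      t <- t + T_st
      x <- x2
    }
    if (t > end_time || pass == passes) break
    if (!arc) {
      add(new_phase("pivot", t, t + p$turn_duration, x, y, x, y,
                    yaw, yaw + pi, segment = "turn"))
      t <- t + p$turn_duration
      yaw <- yaw + pi
      # the foot is back on a straight-line stance position after the pivot
      add_dwell(t, T_st, x, y, yaw, "straight")
      t <- t + T_st
    } else {
      nts <- p$n_turn_steps
      for (j in seq_len(nts)) {
        alpha <- j * pi / nts
        if (going_out) {
          # far cap, centred on (L, r)
          xn <- p$walkway_length + R_f * sin(alpha)
          yn <- r - R_f * cos(alpha)
          yawn <- alpha
        } else {
          # near cap, centred on (0, r)
          xn <- -R_f * sin(alpha)
          yn <- r + R_f * cos(alpha)
          yawn <- pi + alpha
        }
        yawn <- yawn + (yaw - (if (going_out) 0 else pi)) # accumulated laps
        add(new_phase("swing", t, t + T_sw, x, y, xn, yn, yaw, yawn,
                      apex = p$step_height, pitch_amp = p$pitch_amp,
                      segment = "turn"))
        t <- t + T_sw
        seg <- if (j == nts) "straight" else "turn"
        add_dwell(t, T_st, xn, yn, yawn, seg)
        t <- t + T_st
        x <- xn; y <- yn; yaw <- yawn
      }
    }
    dir <- -dir
    y <- if (dir > 0) y_out else y_back
  }
  add_dwell(t, p$tail_s, x, y, yaw, "straight")
  t <- t + p$tail_s
  list(phases = phases, t_end = t)
}

# Evaluate the closed-form kinematics of a phase list on a uniform grid.
sample_phases <- function(phases, ts) {
  n <- length(ts)
  pos <- matrix(0, n, 3L)
  acc <- matrix(0, n, 3L)
  yaw <- numeric(n); yawrate <- numeric(n)
  pitch <- numeric(n); pitchrate <- numeric(n)
  i0 <- 1L
  n_ph <- length(phases)
  for (pi_ in seq_len(n_ph)) {
    ph <- phases[[pi_]]
    i1 <- if (pi_ == n_ph) n else {
      min(n, sum(ts < ph$t1 - 1e-12))
    }
    if (i1 < i0) next
    idx <- i0:i1
    tt <- ts[idx]
    if (ph$type == "dwell") {
      pos[idx, 1L] <- ph$x0; pos[idx, 2L] <- ph$y0
      yaw[idx] <- ph$yaw0
    } else if (ph$type == "pivot") {
      D <- ph$t1 - ph$t0
      tau <- pmin(1, pmax(0, (tt - ph$t0) / D))
      pos[idx, 1L] <- ph$x0; pos[idx, 2L] <- ph$y0
      dpsi <- ph$yaw1 - ph$yaw0
      yaw[idx] <- ph$yaw0 + dpsi * minjerk(tau)
      yawrate[idx] <- dpsi * minjerk_d1(tau) / D
    } else { # swing
      D <- ph$t1 - ph$t0
      tau <- pmin(1, pmax(0, (tt - ph$t0) / D))
      m <- minjerk(tau); m2 <- minjerk_d2(tau) / D^2
      pos[idx, 1L] <- ph$x0 + (ph$x1 - ph$x0) * m
      pos[idx, 2L] <- ph$y0 + (ph$y1 - ph$y0) * m
      pos[idx, 3L] <- ph$apex * bump3(tau)
      acc[idx, 1L] <- (ph$x1 - ph$x0) * m2
      acc[idx, 2L] <- (ph$y1 - ph$y0) * m2
      acc[idx, 3L] <- ph$apex * bump3_d2(tau) / D^2
      dpsi <- ph$yaw1 - ph$yaw0
      yaw[idx] <- ph$yaw0 + dpsi * m
      yawrate[idx] <- dpsi * minjerk_d1(tau) / D
      pitch[idx] <- ph$pitch_amp * bump3(tau)
      pitchrate[idx] <- ph$pitch_amp * bump3_d1(tau) / D
    }
    i0 <- i1 + 1L
  }
  list(pos = pos, acc = acc, yaw = yaw, yawrate = yawrate,
       pitch = pitch, pitchrate = pitchrate)
}

# Exact inverse sensor model: body-frame specific force and angular rate
# from Earth-frame kinematics and the yaw-pitch attitude.
inverse_sensor <- function(kin, g = STANDARD_GRAVITY) {
  cy <- cos(kin$yaw); sy <- sin(kin$yaw)
  cp <- cos(kin$pitch); sp <- sin(kin$pitch)
  ux <- kin$acc[, 1L]; uy <- kin$acc[, 2L]; uz <- kin$acc[, 3L] + g
  u1x <- cy * ux + sy * uy
  u1y <- -sy * ux + cy * uy
  ab <- cbind(cp * u1x - sp * uz, u1y, sp * u1x + cp * uz)
  gb <- cbind(-kin$yawrate * sp, kin$pitchrate, kin$yawrate * cp)
  list(accel = ab, gyro = gb)
}

truth_stances <- function(phases, t_end, min_keep = 0.05) {
  rows <- Filter(function(ph) ph$type == "dwell" && ph$t0 < t_end, phases)
  if (!length(rows)) {
    return(data.frame(t_on = numeric(), t_off = numeric(), x = numeric(),
                      y = numeric(), yaw = numeric(),
                      segment = character()))
  }
  df <- data.frame(
    t_on = vapply(rows, `[[`, numeric(1), "t0"),
    t_off = pmin(vapply(rows, `[[`, numeric(1), "t1"), t_end),
    x = vapply(rows, `[[`, numeric(1), "x0"),
    y = vapply(rows, `[[`, numeric(1), "y0"),
    yaw = vapply(rows, `[[`, numeric(1), "yaw0"),
    segment = vapply(rows, `[[`, character(1), "segment")
  )
  df[df$t_off - df$t_on >= min_keep, , drop = FALSE]
}

#' Simulate a walking test with known ground truth
#'
#' Generates bilateral foot-worn IMU recordings for a back-and-forth walking
#' protocol, together with the exact ground truth every pipeline stage can be
#' checked against.  The left foot lags the right by half a gait cycle; the
#' two feet walk parallel tracks `2 * lateral_offset` apart.
#'
#' @param protocol A [gait_protocol()].
#' @param noise A [noise_model()]; the default is noise-free.
#' @param sample_rate_hz Sampling rate of the generated recordings (128).
#' @return List with `left` and `right` (`imu_recording`s) and `truth`, a
#'   `gait_truth` holding per-foot stance schedules (`t_on`, `t_off`, `x`,
#'   `y`), true chord distances and totals, the true trajectory, attitude and
#'   Earth-frame acceleration, the bilateral true `d_total`, and
#'   `straight_distance` (chords accumulated on the straight segments only).
#' @examples
#' sim <- simulate_walk(gait_protocol(mode = "fixed_time", target = 20),
#'                      noise_model(0, 0))
#' sim$truth$d_total
#' @export
simulate_walk <- function(protocol, noise = noise_model(0, 0),
                          sample_rate_hz = 128) {
  stopifnot(inherits(protocol, "gait_protocol"), inherits(noise, "noise_model"))
  w <- protocol$lateral_offset
  T_cyc <- 1 / protocol$cadence
  sched <- list(
    right = build_foot_phases(protocol, -w, extra_lead = 0),
    left = build_foot_phases(protocol, +w, extra_lead = T_cyc / 2)
  )
  t_end <- if (protocol$mode == "fixed_time") protocol$target else {
    max(sched$right$t_end, sched$left$t_end)
  }
  n <- floor(t_end * sample_rate_hz + 1e-9) + 1L
  ts <- (seq_len(n) - 1L) / sample_rate_hz

  feet <- with_local_seed(noise$seed, {
    lapply(c(right = "right", left = "left"), function(side) {
      kin <- sample_phases(sched[[side]]$phases, ts)
      sig <- inverse_sensor(kin)
      acc <- sig$accel + matrix(noise$accel_bias, n, 3L, byrow = TRUE)
      gyr <- sig$gyro + matrix(noise$gyro_bias, n, 3L, byrow = TRUE)
      if (noise$accel_sd > 0) acc <- acc + matrix(stats::rnorm(3L * n, 0, noise$accel_sd), n, 3L)
      if (noise$gyro_sd > 0) gyr <- gyr + matrix(stats::rnorm(3L * n, 0, noise$gyro_sd), n, 3L)
      rec <- imu_recording(
        ts, acc, gyr,
        sensor_meta(sample_rate_hz = sample_rate_hz, foot_side = side,
                    subject_id = "simulated")
      )
      st <- truth_stances(sched[[side]]$phases, t_end)
      chords <- if (nrow(st) >= 2L) {
        sqrt(diff(st$x)^2 + diff(st$y)^2)
      } else numeric()
      straight <- if (length(chords)) {
        same_heading <- abs(diff(st$yaw)) < 1e-12
        both_straight <- st$segment[-nrow(st)] == "straight" &
          st$segment[-1L] == "straight"
        sum(chords[same_heading & both_straight])
      } else 0
      list(
        recording = rec,
        truth = list(timestamps = ts, position = kin$pos,
                     accel_earth = kin$acc, yaw = kin$yaw, pitch = kin$pitch,
                     stances = st, chords = chords,
                     d_total = sum(chords), straight_distance = straight)
      )
    })
  })

  truth <- structure(
    list(
      left = feet$left$truth,
      right = feet$right$truth,
      d_total = (feet$left$truth$d_total + feet$right$truth$d_total) / 2,
      straight_distance = (feet$left$truth$straight_distance +
                             feet$right$truth$straight_distance) / 2,
      protocol = protocol,
      noise = noise
    ),
    class = "gait_truth"
  )
  list(left = feet$left$recording, right = feet$right$recording, truth = truth)
}

#' @export
print.gait_truth <- function(x, ...) {
  cat(sprintf(
    "<gait_truth> true d_total %.2f m (straight %.2f m); %d/%d foot-flat periods (L/R)\n",
    x$d_total, x$straight_distance, nrow(x$left$stances), nrow(x$right$stances)
  ))
  invisible(x)
}

#' End-to-end error-rate distribution on simulated walks
#'
#' Runs the full pipeline (orientation, ZUPT detection, trajectory, chord
#' distances, bilateral average) on freshly simulated walks, one per seed,
#' and reports the absolute percentage error of the estimated total against
#' the simulator's ground truth.
#'
#' @param protocol A [gait_protocol()].
#' @param noise A [noise_model()] whose seed is replaced per run.
#' @param seeds Integer vector of simulation seeds (one run each).
#' @param params A [walk_params()] pipeline configuration.
#' @param sample_rate_hz Recording sample rate, Hz.
#' @return Data frame with columns `seed`, `d_total`, `truth`, `err_pct`
#'   (`100 |d_total - truth| / truth`).
#' @export
end_to_end_error <- function(protocol, noise = noise_model(),
                             seeds = 1:5, params = walk_params(),
                             sample_rate_hz = 128) {
  if (!length(seeds)) stopf("need at least one seed")
  rows <- lapply(seeds, function(sd) {
    nm <- noise
    nm$seed <- sd
    sim <- simulate_walk(protocol, nm, sample_rate_hz = sample_rate_hz)
    res <- walk_distance(sim$left, sim$right, params = params)
    truth <- sim$truth$d_total
    data.frame(seed = sd, d_total = res$d_total, truth = truth,
               err_pct = 100 * abs(res$d_total - truth) / truth)
  })
  do.call(rbind, rows)
}
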