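test_that("identical protocol and seed give bitwise-identical recordings", {
  p <- gait_protocol(walkway_length = 8, mode = "fixed_time", target = 15)
  nm <- noise_model(0.05, 0.005, seed = 77)
  a <- simulate_walk(p, nm)
  b <- simulate_walk(p, nm)
  expect_identical(a$left$accel, b$left$accel)
  expect_identical(a$right$gyro, b$right$gyro)
  # and a different seed changes the noise
  c_ <- simulate_walk(p, noise_model(0.05, 0.005, seed = 78))
  expect_false(identical(a$left$accel, c_$left$accel))
})

test_that("the fixed-distance protocol lays out exactly the target straight distance", {
  sim <- simulate_walk(gait_protocol(walkway_length = 20, target = 400),
                       noise_model(0, 0))
  expect_equal(sim$truth$straight_distance, 400, tolerance = 1e-12)
  # pivot turns add no chord length, so the true total equals the target
  expect_equal(sim$truth$d_total, 400, tolerance = 1e-12)
  # 20 passes of 15 strides, plus the initial stance and 19 post-turn stances
  expect_identical(nrow(sim$truth$right$stances), 20L * 15L + 1L + 19L)
  # truth self-consistency: chords recompute exactly from stance positions
  st <- sim$truth$right$stances
  expect_equal(sim$truth$right$chords, sqrt(diff(st$x)^2 + diff(st$y)^2),
               tolerance = 1e-15)
  expect_equal(sim$truth$right$d_total, sum(sim$truth$right$chords))
})

test_that("noise-free signals double-integrate back to the true trajectory
           (independent Simpson oracle)", {
  sim <- simulate_walk(
    gait_protocol(walkway_length = 5, mode = "fixed_distance", target = 5,
                  stride_length = 1.25),
    noise_model(0, 0), sample_rate_hz = 256
  )
  rec <- sim$right
  tr <- sim$truth$right
  # rotate body signals to Earth with the true attitude, subtract gravity
  Q <- walkdist:::quat_from_yaw_pitch(tr$yaw, tr$pitch)
  ae <- walkdist:::quat_rotate_rows(Q, rec$accel)
  ae[, 3L] <- ae[, 3L] - g_std
  dt <- 1 / rec$meta$sample_rate_hz
  odd <- seq(1L, n_samples(rec), by = 2L)
  err <- vapply(1:3, function(j) {
    v <- cum_simpson(dt, ae[, j])
    v[seq(2L, length(v), by = 2L)] <- (v[seq(1L, length(v) - 1, by = 2L)] +
                                         v[seq(3L, length(v), by = 2L)]) / 2
    p <- cum_simpson(dt, v) + tr$position[1L, j]
    max(abs(p[odd] - tr$position[odd, j]), na.rm = TRUE)
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 1e-3)
})

test_that("a six-minute fixed-time walk lands in the plausible distance envelope", {
  sim <- simulate_walk(
    gait_protocol(walkway_length = 15, mode = "fixed_time", target = 360),
    noise_model(0, 0)
  )
  expect_gt(sim$truth$d_total, 300)
  expect_lt(sim$truth$d_total, 700)
  expect_equal(duration(sim$left), 360, tolerance = 1 / 128)
})

test_that("stride length exceeding the walkway is refused", {
  expect_error(gait_protocol(walkway_length = 5, stride_length = 2.4,
                             mode = "fixed_time", target = 30),
               NA) # 2.4 < 5: fine
  expect_error(gait_protocol(walkway_length = 4, stride_length = 1),
               "walkway_length")
  expect_error(gait_protocol(stride_length = 3), "stride_length")
  expect_error(gait_protocol(stance_fraction = 0.9), "stance_fraction")
})

test_that("noise-free straight-only walks recover truth within 1% for every seed", {
  err <- end_to_end_error(
    gait_protocol(walkway_length = 10, mode = "fixed_distance", target = 10,
                  stride_length = 1.25),
    noise_model(0, 0), seeds = 1:5
  )
  expect_true(all(err$err_pct < 1))
})

test_that("doubling the gyro noise does not improve the mean error (paired seeds)", {
  p <- gait_protocol(walkway_length = 12, mode = "fixed_time", target = 45)
  lo <- end_to_end_error(p, noise_model(0.05, 0.005), seeds = 1:10)
  hi <- end_to_end_error(p, noise_model(0.05, 0.010), seeds = 1:10)
  expect_gte(mean(hi$err_pct), mean(lo$err_pct))
})

test_that("arc turns produce broader paths whose turn chords add distance", {
  sim <- simulate_walk(
    gait_protocol(walkway_length = 10, mode = "fixed_distance", target = 30,
                  turn_style = "arc"),
    noise_model(0, 0)
  )
  expect_gt(sim$truth$d_total, sim$truth$straight_distance)
  expect_equal(sim$truth$straight_distance, 30, tolerance = 1e-12)
})
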