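make_free_acc <- function(t, acc, fs = 128) {
  structure(list(timestamps = t, accel = acc, sample_rate_hz = fs),
            class = "free_acceleration")
}

test_that("zero acceleration with a full stationary interval stays at the origin", {
  n <- 129L
  t <- (seq_len(n) - 1L) / 128
  fa <- make_free_acc(t, matrix(0, n, 3L))
  flats <- foot_flat_sequence(1L, n, t[n] / 2)
  traj <- integrate_trajectory(fa, flats)
  expect_equal(max(abs(traj$position)), 0)
  expect_equal(max(abs(traj$velocity)), 0)
})

test_that("a symmetric accelerate-decelerate bout lands at the closed-form displacement", {
  fs <- 128
  t <- seq(0, 3, by = 1 / fs)
  n <- length(t)
  a <- numeric(n)
  a[t >= 1 & t < 1.5] <- 2
  a[t >= 1.5 & t < 2] <- -2
  fa <- make_free_acc(t, cbind(a, 0, 0), fs)
  s1 <- max(which(t < 1))
  s2 <- min(which(t >= 2))
  flats <- foot_flat_sequence(c(1L, s2), c(s1, n), c(t[s1] / 2, (t[s2] + t[n]) / 2))
  traj <- integrate_trajectory(fa, flats)
  # closed form: displacement a*T^2 with a = 2, T = 0.5
  d <- stride_distances(traj, flats)
  expect_equal(d, 0.5, tolerance = 1e-3 / 0.5)
  # terminal velocity pinned to zero across the second stance
  expect_lt(max(sqrt(rowSums(traj$velocity[s2:n, ]^2))), 0.05)
})

test_that("ZUPT residual velocity is small inside every applied interval", {
  sim <- ten_stride_sim(noise_model(0.05, 0.005, seed = 5))
  pf <- process_foot(sim$right)
  mask <- stationary_mask(pf$flats, length(pf$trajectory$timestamps))
  vmag <- sqrt(rowSums(pf$trajectory$velocity^2))
  expect_lt(max(vmag[mask]), 0.05)
})

test_that("reconstructed stride displacements match simulator truth within 0.5%", {
  sim <- ten_stride_sim()
  pf <- process_foot(sim$right)
  truth_chords <- sim$truth$right$chords
  expect_identical(length(pf$per_stride), length(truth_chords))
  rel <- abs(pf$per_stride - truth_chords) / truth_chords
  expect_lt(max(rel), 0.005)
})

test_that("per-stride error does not grow with position in a long noisy walk", {
  sim <- simulate_walk(
    gait_protocol(walkway_length = 40, mode = "fixed_distance", target = 40,
                  stride_length = 1.3),
    noise_model(0.05, 0.005, seed = 21)
  )
  pf <- process_foot(sim$right)
  err <- abs(pf$per_stride - sim$truth$right$chords)
  half <- length(err) %/% 2L
  early <- err[seq_len(half)]
  late <- err[(half + 1L):length(err)]
  expect_gt(stats::t.test(early, late)$p.value, 0.01)
})

test_that("trajectory and chords are invariant to a global yaw rotation", {
  sim <- ten_stride_sim()
  rec <- sim$right
  flats <- detect_foot_flat(rec)
  track <- estimate_orientation(rec)
  fa <- free_acceleration(rec, track)
  d0 <- stride_distances(integrate_trajectory(fa, flats), flats)
  for (ang in c(30, 123) * pi / 180) {
    rot <- fa
    ca <- cos(ang); sa <- sin(ang)
    rot$accel <- cbind(
      ca * fa$accel[, 1L] - sa * fa$accel[, 2L],
      sa * fa$accel[, 1L] + ca * fa$accel[, 2L],
      fa$accel[, 3L]
    )
    d1 <- stride_distances(integrate_trajectory(rot, flats), flats)
    expect_equal(d1, d0, tolerance = 1e-9)
  }
})

test_that("an empty foot-flat sequence yields an uncorrected trajectory with a warning", {
  n <- 257L
  t <- (seq_len(n) - 1L) / 128
  fa <- make_free_acc(t, matrix(c(0.1, 0, 0), n, 3L, byrow = TRUE))
  expect_warning(traj <- integrate_trajectory(fa, foot_flat_sequence()),
                 "drift unbounded")
  expect_false(traj$zupt_applied)
})
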