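# Build a trajectory whose positions at given times are exactly `pos`,
# with one foot-flat interval per row.
traj_from_flat_positions <- function(pos, dwell = 0.5, fs = 128) {
  m <- nrow(pos)
  t_rep <- (seq_len(m) - 0.5) * dwell * 2
  n <- round((max(t_rep) + dwell) * fs) + 1L
  t <- (seq_len(n) - 1L) / fs
  idx <- vapply(t_rep, function(tr) which.min(abs(t - tr)), integer(1))
  P <- matrix(0, n, 3L)
  for (i in seq_len(m)) {
    from <- if (i == 1L) 1L else idx[i]
    to <- if (i == m) n else idx[i + 1L] - 1L
    P[from:to, ] <- matrix(pos[i, ], to - from + 1L, 3L, byrow = TRUE)
  }
  flats <- foot_flat_sequence(pmax(1L, idx - 2L), pmin(n, idx + 2L), t_rep)
  list(traj = foot_trajectory(t, P, P * 0), flats = flats)
}

test_that("chord distance ignores the vertical coordinate", {
  x <- traj_from_flat_positions(rbind(c(0, 0, 0), c(3, 4, 0.02)))
  expect_equal(stride_distances(x$traj, x$flats), 5)
  same <- traj_from_flat_positions(rbind(c(1, 2, 0), c(1, 2, 0.1)))
  expect_equal(stride_distances(same$traj, same$flats), 0)
  single <- traj_from_flat_positions(rbind(c(0, 0, 0)))
  expect_identical(stride_distances(single$traj, single$flats), numeric())
})

test_that("chords along a semicircle sum to the exact polygon perimeter,
           below the arc length", {
  theta <- seq(0, pi, length.out = 5L)
  pos <- cbind(cos(theta), sin(theta), 0)
  x <- traj_from_flat_positions(pos)
  d <- stride_distances(x$traj, x$flats)
  expect_equal(sum(d), 4 * 2 * sin(pi / 8), tolerance = 1e-12)
  expect_lt(sum(d), pi)
})

test_that("total distance is the plain sum of chords", {
  expect_equal(total_distance(c(5, 0, 1.25)), 6.25)
  expect_equal(total_distance(numeric()), 0)
})

test_that("bilateral averaging and its degenerate single-foot path", {
  expect_equal(bilateral_total(400, 402), 401)
  expect_warning(one <- bilateral_total(400, NULL), "single foot")
  expect_equal(one, 400)
  expect_error(bilateral_total(NULL, NULL), "no per-foot totals")
})

test_that("the estimated total tracks the simulator's fixed-distance truth", {
  sim <- simulate_walk(
    gait_protocol(walkway_length = 10, mode = "fixed_distance", target = 60,
                  stride_length = 1.25),
    noise_model(0.05, 0.005, seed = 2)
  )
  res <- walk_distance(sim$left, sim$right)
  expect_lt(abs(res$d_total - sim$truth$d_total) / sim$truth$d_total, 0.02)
  expect_true(res$d_total >= min(res$left$total, res$right$total))
  expect_true(res$d_total <= max(res$left$total, res$right$total))
})

test_that("chord sum never exceeds the horizontal arc length", {
  for (style in c("pivot", "arc")) {
    sim <- simulate_walk(
      gait_protocol(walkway_length = 8, mode = "fixed_time", target = 25,
                    turn_style = style),
      noise_model(0.02, 0.002, seed = 4)
    )
    pf <- process_foot(sim$right)
    expect_lte(pf$total, pf$arc_length + 1e-6)
  }
})

test_that("a straight constant-velocity path has equal chord and arc length", {
  n <- 257L
  t <- (seq_len(n) - 1L) / 128
  P <- cbind(t, 0, 0)           # 1 m/s along x
  V <- cbind(rep(1, n), 0, 0)
  traj <- foot_trajectory(t, P, V)
  flats <- foot_flat_sequence(c(1L, n), c(1L, n), c(t[1L], t[n]))
  expect_equal(sum(stride_distances(traj, flats)),
               arc_length_distance(traj, flats), tolerance = 1e-9)
  still <- foot_trajectory(t, P * 0, V * 0)
  expect_equal(arc_length_distance(still), 0)
})

test_that("deleting any interior foot-flat never increases the total (merge property)", {
  sim <- ten_stride_sim()
  pf <- process_foot(sim$right)
  flats <- pf$flats
  d0 <- total_distance(stride_distances(pf$trajectory, flats))
  iv <- flats$intervals
  for (k in seq(2L, flats$n - 1L)) {
    sub <- foot_flat_sequence(iv$start_index[-k], iv$end_index[-k], iv$t_rep[-k])
    dk <- total_distance(stride_distances(pf$trajectory, sub))
    expect_lte(dk, d0 + 1e-9)
    # the merged chord replaces exactly the two chords it bridges
    expect_identical(length(stride_distances(pf$trajectory, sub)),
                     length(stride_distances(pf$trajectory, flats)) - 1L)
  }
})

test_that("chord totals are invariant under rigid horizontal motion", {
  sim <- ten_stride_sim()
  pf <- process_foot(sim$right)
  d0 <- total_distance(stride_distances(pf$trajectory, pf$flats))
  ang <- 77 * pi / 180
  R <- matrix(c(cos(ang), sin(ang), -sin(ang), cos(ang)), 2L)
  moved <- pf$trajectory
  moved$position[, 1:2] <- moved$position[, 1:2] %*% t(R)
  moved$position[, 1L] <- moved$position[, 1L] + 13.7
  moved$position[, 2L] <- moved$position[, 2L] - 4.2
  expect_equal(total_distance(stride_distances(moved, pf$flats)), d0,
               tolerance = 1e-12)
})
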