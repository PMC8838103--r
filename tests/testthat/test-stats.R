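test_that("fixed-distance percentage error reproduces hand arithmetic", {
  # a cohort whose mean absolute error is 7.68 m against a 400 m course
  r <- fixed_distance_error_pct(400 - 7.68, fixed = 400)
  expect_equal(r$absolute_pct, 1.92)
  expect_equal(fixed_distance_error_pct(rep(400, 5))$absolute_pct, 0)
  sym <- fixed_distance_error_pct(c(390, 410))
  expect_equal(sym$absolute_pct, 2.5)
  expect_equal(sym$signed_pct, 0)
  expect_error(fixed_distance_error_pct(numeric()), "empty")
})

test_that("average absolute error rate matches printed cohort summaries", {
  # mean |error| 19.77 m over mean manual 474.42 m
  expect_equal(round(average_absolute_error_rate(474.42, 474.42 - 19.77), 2), 4.17)
  # mean |error| 18.36 m over mean manual 571.68 m
  expect_equal(round(average_absolute_error_rate(571.68, 571.68 - 18.36), 2), 3.21)
  expect_equal(average_absolute_error_rate(c(400, 500), c(400, 500)), 0)
})

test_that("average absolute error rate is scale invariant", {
  set.seed(31)
  manual <- runif(20, 300, 700)
  digital <- manual + rnorm(20, 0, 25)
  r1 <- average_absolute_error_rate(manual, digital)
  r2 <- average_absolute_error_rate(manual * 3.7, digital * 3.7)
  expect_equal(r1, r2, tolerance = 1e-12)
})

test_that("Bland-Altman agrees with hand computation on tiny examples", {
  expect_warning(ba0 <- bland_altman(c(100, 200, 300), c(100, 200, 300)),
                 "zero variance")
  expect_equal(ba0$bias, 0)
  expect_equal(ba0$loa_lower, 0)
  expect_equal(ba0$loa_upper, 0)
  ba <- bland_altman(c(100, 100, 100), c(99, 100, 101))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_lower, -1.96)
  expect_equal(ba$loa_upper, 1.96)
})

test_that("Bland-Altman equals a first-principles computation on a random cohort", {
  set.seed(24)
  manual <- runif(24, 350, 650)
  digital <- manual + rnorm(24, -8, 20)
  ba <- bland_altman(manual, digital)
  # independent brute-force oracle
  d <- digital - manual
  n <- length(d)
  m <- sum(d) / n
  s <- sqrt(sum((d - m)^2) / (n - 1))
  tq <- qt(0.975, n - 1)
  expect_equal(ba$bias, m, tolerance = 1e-12)
  expect_equal(ba$loa_lower, m - 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$loa_upper, m + 1.96 * s, tolerance = 1e-12)
  expect_equal(ba$bias_ci, m + c(-1, 1) * tq * s / sqrt(n), tolerance = 1e-12)
  expect_equal(ba$loa_upper_ci, m + 1.96 * s + c(-1, 1) * tq * sqrt(3 * s^2 / n),
               tolerance = 1e-12)
  # midpoint identity
  expect_equal((ba$loa_upper + ba$loa_lower) / 2, ba$bias, tolerance = 1e-12)
})

test_that("ICC(2,1) is 1 for identical raters and near 0 for independent raters", {
  set.seed(6)
  x <- runif(10, 300, 700)
  expect_equal(icc21(cbind(x, x))$value, 1, tolerance = 1e-12)
  a <- rnorm(200, 500, 80)
  b <- rnorm(200, 500, 80)
  expect_lt(abs(icc21(cbind(a, b))$value), 0.15)
  expect_error(icc21(matrix(5, 4, 2)), "constant")
})

test_that("ICC(2,1) equals an independent ANOVA-based computation", {
  ratings <- rbind(c(9, 2), c(1, 1), c(8, 4), c(6, 4), c(8, 5), c(7, 3))
  r <- icc21(ratings)
  n <- nrow(ratings); k <- ncol(ratings)
  long <- data.frame(
    score = as.vector(ratings),
    subj = factor(rep(seq_len(n), k)),
    rater = factor(rep(seq_len(k), each = n))
  )
  ms <- summary(stats::aov(score ~ subj + rater, data = long))[[1]][["Mean Sq"]]
  msr <- ms[1]; msc <- ms[2]; mse <- ms[3]
  oracle <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  expect_equal(r$value, oracle, tolerance = 1e-12)
  expect_equal(r$msr, msr, tolerance = 1e-12)
  expect_equal(r$mse, mse, tolerance = 1e-12)
})

test_that("ICC(2,1) confidence interval matches an independent reference", {
  # frozen from an external two-way random-effects implementation run on
  # this exact fixture (reported to 2 dp)
  set.seed(42)
  m <- matrix(rnorm(48, 500, 90), 24, 2)
  m[, 2] <- m[, 1] + rnorm(24, -5, 20)
  r <- icc21(m)
  expect_equal(round(r$value, 2), 0.99)
  expect_equal(round(r$ci, 2), c(0.97, 0.99))
})

test_that("ICC(2,1) is shift invariant and degrades with added rater noise", {
  set.seed(13)
  x <- runif(30, 300, 700)
  base <- cbind(x, x + rnorm(30, 0, 10))
  r0 <- icc21(base)$value
  expect_equal(icc21(base + 123.4)$value, r0, tolerance = 1e-12)
  noise_sd <- c(10, 40, 120)
  vals <- vapply(noise_sd, function(s) {
    set.seed(99)
    icc21(cbind(x, x + rnorm(30, 0, s)))$value
  }, numeric(1))
  expect_true(all(diff(vals) < 0))
})

test_that("the agreement report bundles all statistics coherently", {
  set.seed(8)
  manual <- runif(24, 350, 650)
  digital <- manual + rnorm(24, -8, 20)
  rep <- agreement_report(manual, digital)
  expect_equal(rep$mean_abs_error, mean(abs(manual - digital)))
  expect_equal(rep$error_rate_pct,
               100 * mean(abs(manual - digital)) / mean(manual))
  expect_equal(rep$bland_altman$bias, mean(digital - manual))
  expect_equal(rep$icc$value, icc21(cbind(manual, digital))$value)
})
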