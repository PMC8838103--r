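# Agreement statistics between algorithm (digital) and manual walk distances:
# error rates, Bland-Altman limits of agreement, and ICC(2,1).

#' Paired manual and digital distances
#'
#' @param manual Manually measured total distances, metres, one per subject.
#' @param digital Algorithm-estimated total distances, metres, same order.
#' @return A `paired_distances` object with fields `manual`, `digital`, `n`.
#' @export
paired_distances <- function(manual, digital) {
  manual <- as.numeric(manual)
  digital <- as.numeric(digital)
  if (length(manual) != length(digital)) stopf("manual and digital lengths differ")
  if (!length(manual)) stopf("need at least one subject")
  if (anyNA(manual) || anyNA(digital)) stopf("missing values not allowed")
  if (any(manual <= 0) || any(digital <= 0)) stopf("distances must be positive")
  structure(list(manual = manual, digital = digital, n = length(manual)),
            class = "paired_distances")
}

#' Percentage error against a fixed course distance
#'
#' For a fixed-distance protocol (e.g. a 400 m walk) the per-subject error is
#' the difference between the estimated distance and the fixed course length,
#' normalized to that length.  Returns both the mean absolute and the mean
#' signed percentage error.
#'
#' @param digital Estimated distances, metres, one per subject.
#' @param fixed The fixed course distance, metres (default 400).
#' @return List with `absolute_pct` (mean of `100 |fixed - d_j| / fixed`) and
#'   `signed_pct` (mean of `100 (d_j - fixed) / fixed`).
#' @examples
#' fixed_distance_error_pct(c(390, 410), 400)  # 2.5% absolute, 0% signed
#' @export
fixed_distance_error_pct <- function(digital, fixed = 400) {
  if (!length(digital)) stopf("empty input")
  if (fixed <= 0) stopf("fixed distance must be positive")
  list(
    absolute_pct = mean(100 * abs(fixed - digital) / fixed),
    signed_pct = mean(100 * (digital - fixed) / fixed)
  )
}

#' Average absolute error rate against manual distance
#'
#' `100 * mean(|manual_j - digital_j|) / mean(manual_j)`: the cohort's mean
#' absolute distance error as a percentage of its mean manual distance.  This
#' is the headline accuracy metric for fixed-time walk tests, where every
#' subject covers a different true distance.
#'
#' @param pd A [paired_distances()] object, or a numeric vector of manual
#'   distances (then `digital` must be given).
#' @param digital Digital distances when `pd` is a plain vector.
#' @return The error rate, percent.
#' @export
average_absolute_error_rate <- function(pd, digital = NULL) {
  if (!inherits(pd, "paired_distances")) pd <- paired_distances(pd, digital)
  mm <- mean(pd$manual)
  if (mm == 0) stopf("mean manual distance is zero")
  100 * mean(abs(pd$manual - pd$digital)) / mm
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `digital - manual`, so a negative bias means the
#' algorithm underestimates the manual distance.  Limits of agreement are
#' `bias +/- agreement_multiplier * SD(diff)` (sample SD, n - 1).  Confidence
#' intervals use the t distribution: `SE(bias) = SD/sqrt(n)` and
#' `SE(LOA) = sqrt(3 SD^2 / n)`.
#'
#' @param pd A [paired_distances()] object (or manual vector with `digital`).
#' @param digital Digital distances when `pd` is a plain vector.
#' @param agreement_multiplier LOA multiplier (default 1.96).
#' @param conf Confidence level for the CIs (default 0.95).
#' @return A `bland_altman` object: `n`, `bias`, `sd_diff`, `loa_lower`,
#'   `loa_upper`, and `*_ci` two-element vectors (`NA` when `n < 3`).
#' @export
bland_altman <- function(pd, digital = NULL, agreement_multiplier = 1.96,
                         conf = 0.95) {
  if (!inherits(pd, "paired_distances")) pd <- paired_distances(pd, digital)
  n <- pd$n
  if (n < 2L) stopf("Bland-Altman needs at least 2 subjects")
  d <- pd$digital - pd$manual
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa_lower <- bias - agreement_multiplier * sdd
  loa_upper <- bias + agreement_multiplier * sdd
  degenerate <- sdd == 0
  if (n >= 3L && !degenerate) {
    tq <- stats::qt(1 - (1 - conf) / 2, df = n - 1L)
    se_bias <- sdd / sqrt(n)
    se_loa <- sqrt(3 * sdd^2 / n)
    bias_ci <- bias + c(-1, 1) * tq * se_bias
    loa_lower_ci <- loa_lower + c(-1, 1) * tq * se_loa
    loa_upper_ci <- loa_upper + c(-1, 1) * tq * se_loa
  } else {
    bias_ci <- loa_lower_ci <- loa_upper_ci <- c(NA_real_, NA_real_)
    if (degenerate) warnf("zero variance of differences: LOAs collapse to the bias")
  }
  structure(
    list(n = n, bias = bias, sd_diff = sdd,
         loa_lower = loa_lower, loa_upper = loa_upper,
         bias_ci = bias_ci, loa_lower_ci = loa_lower_ci,
         loa_upper_ci = loa_upper_ci,
         agreement_multiplier = agreement_multiplier, conf = conf,
         mean_pair = (pd$manual + pd$digital) / 2, diff = d),
    class = "bland_altman"
  )
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf(
    "Bland-Altman (digital - manual), n = %d\n  bias %.2f m [%.2f, %.2f]\n  LOA  %.2f m [%.2f, %.2f] to %.2f m [%.2f, %.2f]\n",
    x$n, x$bias, x$bias_ci[1L], x$bias_ci[2L],
    x$loa_lower, x$loa_lower_ci[1L], x$loa_lower_ci[2L],
    x$loa_upper, x$loa_upper_ci[1L], x$loa_upper_ci[2L]
  ))
  invisible(x)
}

#' Bland-Altman plot
#'
#' Mean of the paired measurements against their difference, with horizontal
#' lines at the bias (blue) and the upper (green) and lower (red) limits of
#' agreement.
#'
#' @param x A `bland_altman` object.
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot_bland_altman <- function(x, ...) {
  graphics::plot(x$mean_pair, x$diff,
                 xlab = "Mean of manual and digital distance (m)",
                 ylab = "Digital - manual distance (m)", pch = 19, ...)
  graphics::abline(h = x$bias, col = "blue", lwd = 2)
  graphics::abline(h = x$loa_upper, col = "green4", lwd = 2, lty = 2)
  graphics::abline(h = x$loa_lower, col = "red", lwd = 2, lty = 2)
  invisible(x)
}

#' Intraclass correlation ICC(2,1) with confidence interval
#'
#' Two-way random-effects, absolute-agreement, single-measure intraclass
#' correlation from the standard ANOVA decomposition of an n x k ratings
#' matrix (subjects in rows, raters in columns):
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k (MSC - MSE) / n)`.
#' The confidence interval uses the exact F-based formulas of McGraw and
#' Wong for the absolute-agreement single-rater case.
#'
#' @param ratings Numeric matrix, subjects x raters (k >= 2).
#' @param conf Confidence level (default 0.95).
#' @return An `icc` object: `value`, `ci` (length 2), `n`, `k`, and the mean
#'   squares `msr`, `msc`, `mse`.
#' @export
icc21 <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L) stopf("need at least 2 subjects and 2 raters")
  if (anyNA(ratings)) stopf("missing ratings not supported")
  grand <- mean(ratings)
  row_m <- rowMeans(ratings)
  col_m <- colMeans(ratings)
  ss_rows <- k * sum((row_m - grand)^2)
  ss_cols <- n * sum((col_m - grand)^2)
  ss_tot <- sum((ratings - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  msr <- ss_rows / (n - 1)
  msc <- ss_cols / (k - 1)
  mse <- ss_err / ((n - 1) * (k - 1))
  if (msr <= .Machine$double.eps && mse <= .Machine$double.eps) {
    stopf("constant ratings matrix: ICC undefined (no between-subject variance)")
  }
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)

  # McGraw-Wong CI for single-rater absolute agreement
  alpha <- 1 - conf
  r <- icc
  a <- k * r / (n * (1 - r))
  b <- 1 + k * r * (n - 1) / (n * (1 - r))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  lower <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  upper <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(
    list(value = icc, ci = c(lower, upper), n = n, k = k,
         msr = msr, msc = msc, mse = mse, conf = conf),
    class = "icc"
  )
}

#' @export
print.icc <- function(x, ...) {
  cat(sprintf("ICC(2,1) = %.3f [%.3f, %.3f], n = %d subjects, k = %d raters\n",
              x$value, x$ci[1L], x$ci[2L], x$n, x$k))
  invisible(x)
}

#' Full agreement report between manual and digital distances
#'
#' Bundles the mean absolute error, the average absolute error rate, the
#' Bland-Altman bias and limits of agreement, and ICC(2,1), as used to
#' validate walk-distance algorithms against the manual clinical standard.
#'
#' @param pd A [paired_distances()] object (or manual vector with `digital`).
#' @param digital Digital distances when `pd` is a plain vector.
#' @param conf Confidence level (default 0.95).
#' @return An `agreement_report` object.
#' @export
agreement_report <- function(pd, digital = NULL, conf = 0.95) {
  if (!inherits(pd, "paired_distances")) pd <- paired_distances(pd, digital)
  ba <- bland_altman(pd, conf = conf)
  icc <- tryCatch(icc21(cbind(pd$manual, pd$digital), conf = conf),
                  error = function(e) NULL)
  structure(
    list(
      n = pd$n,
      mean_abs_error = mean(abs(pd$manual - pd$digital)),
      error_rate_pct = average_absolute_error_rate(pd),
      bland_altman = ba,
      icc = icc
    ),
    class = "agreement_report"
  )
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d)\n", x$n))
  cat(sprintf("  mean |error|          %.2f m\n", x$mean_abs_error))
  cat(sprintf("  abs. error rate       %.2f %%\n", x$error_rate_pct))
  print(x$bland_altman)
  if (!is.null(x$icc)) print(x$icc)
  invisible(x)
}
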