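# Per-stride horizontal chord distances and walk totals.
#
# The core definition: if the foot is flat and still at representative times
# t_i and t_{i+1} of consecutive foot-flat periods, the distance credited to
# that stride is the horizontal chord
#   d_i = sqrt( (x(t_{i+1}) - x(t_i))^2 + (y(t_{i+1}) - y(t_i))^2 ),
# the vertical coordinate being ignored.  The walk total is the plain sum of
# chords, turns included; the reported distance is the average of the two
# feet's totals.

#' Per-stride horizontal chord distances
#'
#' Reads the trajectory position at each foot-flat representative time
#' (nearest sample, no sub-sample interpolation: the foot is still during
#' stance so the position is constant to first order) and returns the
#' horizontal straight-line distance between consecutive foot-flat positions.
#'
#' @param traj A `foot_trajectory`.
#' @param flats The matching `foot_flat_sequence`.
#' @return Numeric vector of `N - 1` chord distances (metres); empty when
#'   fewer than two foot-flat periods exist.
#' @export
stride_distances <- function(traj, flats) {
  if (flats$n < 2L) return(numeric())
  t <- traj$timestamps
  idx <- vapply(flats$intervals$t_rep,
                function(tr) which.min(abs(t - tr)), integer(1))
  pos <- traj$position[idx, , drop = FALSE]
  dx <- diff(pos[, 1L])
  dy <- diff(pos[, 2L])
  sqrt(dx^2 + dy^2)
}

#' Total walk distance from per-stride chords
#'
#' @param per_stride Numeric vector of chord distances, metres.
#' @return Their sum; 0 for an empty walk.
#' @export
total_distance <- function(per_stride) {
  if (!length(per_stride)) return(0)
  sum(per_stride)
}

#' Bilateral average of per-foot walk totals
#'
#' The reported walk distance is the arithmetic mean of the totals estimated
#' independently from the left and the right foot.  If only one foot is
#' available its total is returned with a warning.
#'
#' @param left,right Per-foot total distances (metres), either may be `NULL`.
#' @return The bilateral total, metres.
#' @export
bilateral_total <- function(left = NULL, right = NULL) {
  have_l <- !is.null(left) && is.finite(left)
  have_r <- !is.null(right) && is.finite(right)
  if (!have_l && !have_r) stopf("no per-foot totals available")
  if (have_l && have_r) return((left + right) / 2)
  warnf("only one foot available: bilateral total falls back to a single foot")
  if (have_l) left else right
}

#' Horizontal arc length of a trajectory
#'
#' Integrates the horizontal velocity magnitude over time (trapezoidal rule).
#' This follows the full curvature of the foot path between steps, so for any
#' walk it is at least as long as the chord-sum distance; it is implemented
#' for comparison, not as the reported distance.
#'
#' @param traj A `foot_trajectory`.
#' @param flats Optional `foot_flat_sequence`; when supplied the integral is
#'   restricted to the span from the first to the last foot-flat interval
#'   (the same span the chords cover).
#' @return Arc length, metres.
#' @export
arc_length_distance <- function(traj, flats = NULL) {
  t <- traj$timestamps
  v <- sqrt(traj$velocity[, 1L]^2 + traj$velocity[, 2L]^2)
  if (!is.null(flats) && flats$n > 0L) {
    iv <- flats$intervals
    keep <- iv$start_index[1L]:iv$end_index[flats$n]
    t <- t[keep]
    v <- v[keep]
  }
  trapz(t, v)
}
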