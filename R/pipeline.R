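# End-to-end pipeline: recording -> orientation -> ZUPT -> trajectory ->
# per-stride chords -> per-foot totals -> bilateral average.

#' Pipeline configuration
#'
#' @param orientation An [orientation_params()] object.
#' @param zupt A [zupt_params()] object.
#' @param qc_foot_discrepancy_pct If the two feet's totals differ by more
#'   than this percentage of their mean, a quality warning is attached to the
#'   result (they are still averaged).
#' @param jitter_tol Timestamp jitter tolerance (fraction of the nominal
#'   sample period) beyond which inputs are resampled before processing.
#' @return A `walk_params` list.
#' @export
walk_params <- function(orientation = orientation_params(),
                        zupt = zupt_params(),
                        qc_foot_discrepancy_pct = 10,
                        jitter_tol = 0.1) {
  structure(
    list(orientation = orientation, zupt = zupt,
         qc_foot_discrepancy_pct = qc_foot_discrepancy_pct,
         jitter_tol = jitter_tol),
    class = "walk_params"
  )
}

#' Process one foot's recording to per-stride distances
#'
#' Runs the single-foot chain: (optional) resampling, foot-flat detection,
#' gyro-bias estimation over the detected stationary samples, orientation
#' fusion, Earth-frame gravity removal, ZUPT-corrected integration and chord
#' distances.
#'
#' @param rec An `imu_recording`.
#' @param params A [walk_params()] configuration.
#' @return List with `per_stride`, `total`, `n_flats`, `flats`, `trajectory`,
#'   `arc_length`, and `warnings` (character vector).
#' @export
process_foot <- function(rec, params = walk_params()) {
  validate_recording(rec)
  warns <- character()
  if (!is_uniform(rec, params$jitter_tol)) {
    rec <- resample_uniform(rec)
    warns <- c(warns, "timestamp jitter above tolerance: resampled to a uniform grid")
  }
  flats <- detect_foot_flat(rec, params$zupt)
  bias <- estimate_gyro_bias(rec, flats)
  track <- estimate_orientation(rec, params$orientation, gyro_bias = bias)
  fa <- free_acceleration(rec, track, g = params$orientation$g)
  traj <- withCallingHandlers(
    integrate_trajectory(fa, flats),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  d <- stride_distances(traj, flats)
  list(
    per_stride = d,
    total = total_distance(d),
    n_flats = flats$n,
    flats = flats,
    trajectory = traj,
    arc_length = arc_length_distance(traj, flats),
    warnings = warns
  )
}

#' Estimate the total walk distance from bilateral foot recordings
#'
#' The main entry point: runs [process_foot()] on each available foot and
#' reports the bilateral average of the per-foot chord-sum totals.
#'
#' @param left,right `imu_recording`s; either (but not both) may be `NULL`.
#' @param params A [walk_params()] configuration.
#' @return A `walk_distance_result`: per-foot results (`left`, `right`),
#'   `d_total` (metres), and `warnings`.
#' @examples
#' sim <- simulate_walk(gait_protocol(mode = "fixed_time", target = 20),
#'                      noise_model(0, 0))
#' res <- walk_distance(sim$left, sim$right)
#' res$d_total
#' @export
walk_distance <- function(left = NULL, right = NULL, params = walk_params()) {
  if (is.null(left) && is.null(right)) stopf("supply at least one foot recording")
  warns <- character()
  res_l <- if (!is.null(left)) process_foot(left, params)
  res_r <- if (!is.null(right)) process_foot(right, params)
  warns <- c(warns, res_l$warnings, res_r$warnings)
  tot_l <- res_l$total
  tot_r <- res_r$total
  single_foot <- is.null(tot_l) || is.null(tot_r)
  d_total <- withCallingHandlers(
    bilateral_total(tot_l, tot_r),
    warning = function(w) {
      warns <<- c(warns, conditionMessage(w))
      invokeRestart("muffleWarning")
    }
  )
  if (!single_foot) {
    m <- (tot_l + tot_r) / 2
    if (m > 0 && 100 * abs(tot_l - tot_r) / m > params$qc_foot_discrepancy_pct) {
      warns <- c(warns, sprintf(
        "per-foot totals differ by more than %.0f%% (left %.2f m, right %.2f m)",
        params$qc_foot_discrepancy_pct, tot_l, tot_r))
    }
  }
  structure(
    list(left = res_l, right = res_r, d_total = d_total,
         single_foot = single_foot, warnings = unique(warns)),
    class = "walk_distance_result"
  )
}

#' @export
print.walk_distance_result <- function(x, ...) {
  cat("Walk distance estimate\n")
  if (!is.null(x$left)) {
    cat(sprintf("  left : %8.2f m over %d foot-flat periods\n",
                x$left$total, x$left$n_flats))
  }
  if (!is.null(x$right)) {
    cat(sprintf("  right: %8.2f m over %d foot-flat periods\n",
                x$right$total, x$right$n_flats))
  }
  cat(sprintf("  d_total (bilateral): %.2f m\n", x$d_total))
  for (w in x$warnings) cat(sprintf("  warning: %s\n", w))
  invisible(x)
}

#' Serialize a walk distance result to JSON
#'
#' @param res A `walk_distance_result`.
#' @param path Output path; `NULL` returns the JSON string.
#' @return The path (or JSON string), invisibly.
#' @export
write_result_json <- function(res, path = NULL) {
  payload <- list(
    d_total_m = res$d_total,
    single_foot = res$single_foot,
    left = if (!is.null(res$left)) list(
      total_m = res$left$total, n_foot_flat = res$left$n_flats,
      per_stride_m = res$left$per_stride
    ),
    right = if (!is.null(res$right)) list(
      total_m = res$right$total, n_foot_flat = res$right$n_flats,
      per_stride_m = res$right$per_stride
    ),
    warnings = res$warnings
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(invisible(as.character(json)))
  writeLines(json, path)
  invisible(path)
}
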