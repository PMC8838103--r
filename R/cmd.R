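# Command wrappers: the functions behind the `walkdist` command-line script
# (inst/cli/walkdist.R).  Each takes file paths in, writes JSON out, and
# returns the underlying result object invisibly.

#' Compute a walk distance from recording files
#'
#' Reads one or two per-foot CSV recordings, runs the full pipeline and
#' writes the result as JSON.
#'
#' @param left_path,right_path Paths to per-foot CSV recordings (either may
#'   be `NULL`, not both).
#' @param out Output JSON path (`NULL`: no file written).
#' @param params A [walk_params()] configuration.
#' @return The `walk_distance_result`, invisibly.
#' @export
cmd_distance <- function(left_path = NULL, right_path = NULL, out = NULL,
                         params = walk_params()) {
  if (is.null(left_path) && is.null(right_path)) {
    stopf("supply at least one recording path")
  }
  left <- if (!is.null(left_path)) read_imu_csv(left_path)
  right <- if (!is.null(right_path)) read_imu_csv(right_path)
  res <- suppressWarnings(walk_distance(left, right, params = params))
  if (!is.null(out)) write_result_json(res, out)
  invisible(res)
}

#' Simulate a walk and write recordings plus ground truth
#'
#' @param out_dir Directory for `left.csv`, `right.csv` and `truth.json`.
#' @param protocol A [gait_protocol()].
#' @param noise A [noise_model()].
#' @param seed Optional seed overriding `noise$seed`.
#' @param sample_rate_hz Recording sample rate.
#' @return The simulation list (invisibly), as from [simulate_walk()].
#' @export
cmd_simulate <- function(out_dir, protocol = gait_protocol(),
                         noise = noise_model(), seed = NULL,
                         sample_rate_hz = 128) {
  if (!is.null(seed)) noise$seed <- seed
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- simulate_walk(protocol, noise, sample_rate_hz = sample_rate_hz)
  write_imu_csv(sim$left, file.path(out_dir, "left.csv"))
  write_imu_csv(sim$right, file.path(out_dir, "right.csv"))
  truth <- list(
    d_total_m = sim$truth$d_total,
    straight_distance_m = sim$truth$straight_distance,
    left = list(d_total_m = sim$truth$left$d_total,
                n_foot_flat = nrow(sim$truth$left$stances),
                chords_m = sim$truth$left$chords),
    right = list(d_total_m = sim$truth$right$d_total,
                 n_foot_flat = nrow(sim$truth$right$stances),
                 chords_m = sim$truth$right$chords)
  )
  writeLines(jsonlite::toJSON(truth, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "truth.json"))
  invisible(sim)
}

#' Validate digital against manual distances from a pairs CSV
#'
#' Consumes a CSV with columns `subject_id,manual_m,digital_m`, computes the
#' full agreement report (error rate, Bland-Altman, ICC(2,1)) and optionally
#' writes a JSON report and a Bland-Altman plot.
#'
#' @param pairs_csv Path to the pairs CSV.
#' @param out Output JSON path (`NULL`: none).
#' @param plot_file Optional PNG path for the Bland-Altman plot.
#' @param conf Confidence level.
#' @return The `agreement_report`, invisibly.
#' @export
cmd_validate <- function(pairs_csv, out = NULL, plot_file = NULL, conf = 0.95) {
  df <- utils::read.csv(pairs_csv, stringsAsFactors = FALSE)
  need <- c("subject_id", "manual_m", "digital_m")
  if (!all(need %in% names(df))) {
    stopf("pairs CSV must have columns %s", paste(need, collapse = ", "))
  }
  pd <- paired_distances(df$manual_m, df$digital_m)
  small_n <- pd$n < 3L
  rep <- withCallingHandlers(
    agreement_report(pd, conf = conf),
    warning = function(w) invokeRestart("muffleWarning")
  )
  if (small_n) {
    warnf("n < 3: confidence intervals omitted from the report")
  }
  if (!is.null(out)) {
    ba <- rep$bland_altman
    payload <- list(
      n = rep$n,
      mean_abs_error_m = rep$mean_abs_error,
      error_rate_pct = rep$error_rate_pct,
      bias_m = ba$bias,
      bias_ci = if (!small_n) ba$bias_ci,
      loa_lower_m = ba$loa_lower,
      loa_lower_ci = if (!small_n) ba$loa_lower_ci,
      loa_upper_m = ba$loa_upper,
      loa_upper_ci = if (!small_n) ba$loa_upper_ci,
      icc21 = if (!is.null(rep$icc)) rep$icc$value,
      icc21_ci = if (!is.null(rep$icc) && !small_n) rep$icc$ci
    )
    writeLines(jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                                null = "null"), out)
  }
  if (!is.null(plot_file)) {
    grDevices::png(plot_file, width = 700, height = 500)
    plot_bland_altman(rep$bland_altman,
                      main = sprintf("Bland-Altman agreement (n = %d)", rep$n))
    grDevices::dev.off()
  }
  invisible(rep)
}
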