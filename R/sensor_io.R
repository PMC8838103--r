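#' Sensor metadata for a per-foot IMU recording
#'
#' Describes one foot-worn inertial measurement unit stream: nominal sample
#' rate, which foot the sensor is strapped to, and the units the raw file
#' declares.  Readers convert declared units to the canonical internal units
#' (m/s^2 for acceleration, rad/s for angular rate) on ingest.
#'
#' @param sample_rate_hz Nominal sampling rate in Hz (default 128).
#' @param foot_side `"left"`, `"right"` or `"unknown"`.
#' @param subject_id Opaque subject label.
#' @param accel_unit Declared accelerometer unit, `"m/s^2"` or `"g"`.
#' @param gyro_unit Declared gyroscope unit, `"rad/s"` or `"deg/s"`.
#' @return A `sensor_meta` list.
#' @export
sensor_meta <- function(sample_rate_hz = 128,
                        foot_side = c("unknown", "left", "right"),
                        subject_id = NA_character_,
                        accel_unit = c("m/s^2", "g"),
                        gyro_unit = c("rad/s", "deg/s")) {
  foot_side <- match.arg(foot_side)
  accel_unit <- match.arg(accel_unit)
  gyro_unit <- match.arg(gyro_unit)
  if (!is.numeric(sample_rate_hz) || length(sample_rate_hz) != 1L ||
      !is.finite(sample_rate_hz) || sample_rate_hz <= 0) {
    stopf("sample_rate_hz must be a single positive number")
  }
  structure(
    list(
      sample_rate_hz = as.numeric(sample_rate_hz),
      foot_side = foot_side,
      subject_id = subject_id,
      accel_unit = accel_unit,
      gyro_unit = gyro_unit
    ),
    class = "sensor_meta"
  )
}

#' Construct a validated IMU recording
#'
#' An `imu_recording` holds the body-frame, gravity-inclusive accelerometer
#' signal and the body-frame gyroscope signal of one foot sensor, on a shared
#' strictly increasing time base.  Signals are stored in canonical units
#' (m/s^2 and rad/s); unit conversion happens in the readers, driven by the
#' declared metadata units.
#'
#' @param timestamps Numeric vector of sample times in seconds, strictly
#'   increasing, length >= 2.
#' @param accel N x 3 numeric matrix, m/s^2, body frame, includes gravity.
#' @param gyro N x 3 numeric matrix, rad/s, body frame.
#' @param meta A [sensor_meta()] object.
#' @return An `imu_recording` object.
#' @seealso [read_imu_csv()], [resample_uniform()]
#' @export
imu_recording <- function(timestamps, accel, gyro, meta = sensor_meta()) {
  accel <- as.matrix(accel)
  gyro <- as.matrix(gyro)
  rec <- structure(
    list(
      timestamps = as.numeric(timestamps),
      accel = accel,
      gyro = gyro,
      meta = meta
    ),
    class = "imu_recording"
  )
  validate_recording(rec)
  rec
}

#' Validate an IMU recording against its invariants
#'
#' Checks that timestamps are strictly increasing, lengths agree, all values
#' are finite, and timestamp jitter stays below `jitter_tol` times the nominal
#' sample period.  A recording whose jitter exceeds the tolerance must be
#' passed through [resample_uniform()] before orientation estimation or
#' integration.
#'
#' @param rec An `imu_recording`.
#' @param jitter_tol Maximum allowed |dt - 1/f_nominal| as a fraction of the
#'   nominal sample period (default 0.1).
#' @return `rec`, invisibly; errors on violation.
#' @export
validate_recording <- function(rec, jitter_tol = 0.1) {
  if (!inherits(rec, "imu_recording")) stopf("not an imu_recording")
  t <- rec$timestamps
  n <- length(t)
  if (n < 2L) stopf("recording must contain at least 2 samples, got %d", n)
  if (!is.matrix(rec$accel) || !is.matrix(rec$gyro) ||
      ncol(rec$accel) != 3L || ncol(rec$gyro) != 3L) {
    stopf("accel and gyro must be N x 3 matrices")
  }
  if (nrow(rec$accel) != n || nrow(rec$gyro) != n) {
    stopf("timestamps (%d), accel (%d) and gyro (%d) lengths differ",
          n, nrow(rec$accel), nrow(rec$gyro))
  }
  if (anyNA(t) || any(!is.finite(t))) stopf("non-finite timestamps")
  if (any(!is.finite(rec$accel)) || any(!is.finite(rec$gyro))) {
    stopf("non-finite signal values")
  }
  if (any(diff(t) <= 0)) stopf("timestamps must be strictly increasing")
  if (!inherits(rec$meta, "sensor_meta")) stopf("meta must be a sensor_meta")
  invisible(rec)
}

#' @export
print.imu_recording <- function(x, ...) {
  cat(sprintf(
    "<imu_recording> %d samples, %.3f s, nominal %.6g Hz, foot=%s\n",
    n_samples(x), duration(x), x$meta$sample_rate_hz, x$meta$foot_side
  ))
  invisible(x)
}

#' Number of samples in a recording
#' @param rec An `imu_recording`.
#' @return Integer sample count.
#' @export
n_samples <- function(rec) length(rec$timestamps)

#' Duration of a recording in seconds
#' @param rec An `imu_recording`.
#' @return Last minus first timestamp, seconds.
#' @export
duration <- function(rec) {
  t <- rec$timestamps
  t[length(t)] - t[1L]
}

#' Is a recording uniformly sampled within tolerance?
#'
#' @param rec An `imu_recording`.
#' @param jitter_tol Fraction of the nominal sample period (default 0.1).
#' @return `TRUE` if every sample interval is within tolerance of the nominal
#'   period, else `FALSE` (downstream stages then require resampling).
#' @export
is_uniform <- function(rec, jitter_tol = 0.1) {
  dt <- diff(rec$timestamps)
  period <- 1 / rec$meta$sample_rate_hz
  all(abs(dt - period) <= jitter_tol * period)
}

unit_scale_accel <- function(unit) {
  switch(unit, "m/s^2" = 1, "g" = 9.80665,
         stopf("unsupported accel unit '%s'", unit))
}

unit_scale_gyro <- function(unit) {
  switch(unit, "rad/s" = 1, "deg/s" = pi / 180,
         stopf("unsupported gyro unit '%s'", unit))
}

#' Read a per-foot IMU recording from CSV
#'
#' The interchange format is a comma-separated file with header columns
#' `t,ax,ay,az,gx,gy,gz` and optional leading comment lines of the form
#' `# key: value` declaring metadata (`sample_rate_hz`, `foot_side`,
#' `subject_id`, `accel_unit`, `gyro_unit`).  Declared units are converted to
#' canonical m/s^2 and rad/s; undeclared metadata fall back to the
#' [sensor_meta()] defaults.
#'
#' @param path Path to the CSV file.
#' @return A validated `imu_recording` in canonical units.
#' @examples
#' rec <- imu_recording(seq(0, 1, by = 1 / 128),
#'                      matrix(c(0, 0, 9.80665), 129, 3, byrow = TRUE),
#'                      matrix(0, 129, 3))
#' f <- tempfile(fileext = ".csv")
#' write_imu_csv(rec, f)
#' rec2 <- read_imu_csv(f)
#' @export
read_imu_csv <- function(path) {
  if (!file.exists(path)) stopf("file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^#", lines, value = TRUE)
  meta_kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_]+)\\s*:\\s*(.+?)\\s*$", h))[[1L]]
    if (length(m) == 3L) meta_kv[[m[2L]]] <- m[3L]
  }
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  if (length(body) < 1L) stopf("no data rows in %s", path)
  df <- tryCatch(
    utils::read.csv(text = paste(body, collapse = "\n"),
                    stringsAsFactors = FALSE),
    error = function(e) stopf("malformed CSV in %s: %s", path, conditionMessage(e))
  )
  need <- c("t", "ax", "ay", "az", "gx", "gy", "gz")
  if (!all(need %in% names(df))) {
    stopf("missing columns in %s: %s", path,
          paste(setdiff(need, names(df)), collapse = ", "))
  }
  for (col in need) {
    if (!is.numeric(df[[col]])) stopf("column %s is not numeric in %s", col, path)
  }
  meta <- sensor_meta(
    sample_rate_hz = as.numeric(meta_kv$sample_rate_hz %||% 128),
    foot_side = meta_kv$foot_side %||% "unknown",
    subject_id = meta_kv$subject_id %||% NA_character_,
    accel_unit = meta_kv$accel_unit %||% "m/s^2",
    gyro_unit = meta_kv$gyro_unit %||% "rad/s"
  )
  acc <- as.matrix(df[, c("ax", "ay", "az")]) * unit_scale_accel(meta$accel_unit)
  gyr <- as.matrix(df[, c("gx", "gy", "gz")]) * unit_scale_gyro(meta$gyro_unit)
  dimnames(acc) <- NULL
  dimnames(gyr) <- NULL
  # stored signals are canonical from here on
  meta$accel_unit <- "m/s^2"
  meta$gyro_unit <- "rad/s"
  imu_recording(df$t, acc, gyr, meta)
}

#' Write a per-foot IMU recording to CSV
#'
#' Writes the canonical-unit signals with metadata as `# key: value` comment
#' lines, in the layout that [read_imu_csv()] parses.  Values are printed with
#' enough significant digits that a round trip changes signals by less than
#' 1e-6 m/s^2 (rad/s).
#'
#' @param rec A valid `imu_recording`.
#' @param path Output path.
#' @param digits Significant digits for signal values (default 10).
#' @return `path`, invisibly.
#' @export
write_imu_csv <- function(rec, path, digits = 10) {
  validate_recording(rec)
  con <- file(path, open = "wt")
  on.exit(close(con))
  m <- rec$meta
  writeLines(c(
    sprintf("# sample_rate_hz: %.10g", m$sample_rate_hz),
    sprintf("# foot_side: %s", m$foot_side),
    if (!is.na(m$subject_id)) sprintf("# subject_id: %s", m$subject_id),
    "# accel_unit: m/s^2",
    "# gyro_unit: rad/s",
    "t,ax,ay,az,gx,gy,gz"
  ), con)
  fmt <- function(x) formatC(x, digits = digits, format = "g")
  rows <- paste(
    fmt(rec$timestamps),
    fmt(rec$accel[, 1L]), fmt(rec$accel[, 2L]), fmt(rec$accel[, 3L]),
    fmt(rec$gyro[, 1L]), fmt(rec$gyro[, 2L]), fmt(rec$gyro[, 3L]),
    sep = ","
  )
  writeLines(rows, con)
  invisible(path)
}

#' Resample a recording onto an exactly uniform time base
#'
#' Linear interpolation of every channel onto `seq(t[1], t[n])` at
#' `target_rate`.  The time span is preserved to within one sample period.
#' Required before orientation estimation whenever timestamp jitter exceeds
#' the tolerance checked by [is_uniform()].
#'
#' @param rec An `imu_recording`.
#' @param target_rate Target sampling rate, Hz.
#' @return A new `imu_recording` with exactly uniform timestamps.
#' @export
resample_uniform <- function(rec, target_rate = rec$meta$sample_rate_hz) {
  validate_recording(rec)
  if (target_rate <= 0) stopf("target_rate must be positive")
  t <- rec$timestamps
  dt <- 1 / target_rate
  nt <- floor((t[length(t)] - t[1L]) / dt + 1e-9) + 1L
  tt <- t[1L] + (seq_len(nt) - 1L) * dt
  interp <- function(col) stats::approx(t, col, xout = tt, rule = 2)$y
  acc <- vapply(1:3, function(j) interp(rec$accel[, j]), numeric(nt))
  gyr <- vapply(1:3, function(j) interp(rec$gyro[, j]), numeric(nt))
  meta <- rec$meta
  meta$sample_rate_hz <- target_rate
  imu_recording(tt, acc, gyr, meta)
}
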