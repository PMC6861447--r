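# Trial containers and the delimited-text dialect.
#
# Trials are stored as comma-separated files with a '#'-prefixed key:value
# header (format, trial_id, task, rate, units). Timestamps are seconds from
# trial start. Missing marker samples are empty fields, never sentinel
# numbers.

new_imu_trial <- function(df, rate, task, trial_id) {
  structure(df, rate = rate, task = task, trial_id = trial_id,
            class = c("imu_trial", "data.frame"))
}

new_marker_trial <- function(df, rate, task, trial_id) {
  structure(df, rate = rate, task = task, trial_id = trial_id,
            class = c("marker_trial", "data.frame"))
}

trial_rate <- function(trial) attr(trial, "rate")
trial_task <- function(trial) attr(trial, "task")
trial_id <- function(trial) attr(trial, "trial_id")

#' @export
print.imu_trial <- function(x, ...) {
  cat(sprintf("<imu_trial> id=%s task=%s n=%d rate=%g Hz (%.2f s)\n",
              trial_id(x), trial_task(x), nrow(x), trial_rate(x),
              if (nrow(x)) x$t[nrow(x)] else 0))
  invisible(x)
}

#' @export
print.marker_trial <- function(x, ...) {
  nmiss <- sum(is.na(x$x))
  cat(sprintf("<marker_trial> id=%s task=%s n=%d rate=%g Hz, %d missing frames\n",
              trial_id(x), trial_task(x), nrow(x), trial_rate(x), nmiss))
  invisible(x)
}

write_trial_file <- function(df, path, format, rate, task, id, units) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# format: reachkin-%s", format),
               sprintf("# trial_id: %s", id),
               sprintf("# task: %s", task),
               sprintf("# rate: %.10g", rate),
               sprintf("# units: %s", units)), con)
  out <- df
  for (k in seq_along(out)) out[[k]] <- sprintf("%.17g", out[[k]])
  for (k in seq_along(out)) out[[k]][out[[k]] %in% c("NA", "nan")] <- ""
  write.csv(out, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

read_trial_header <- function(path) {
  lines <- readLines(path, n = 50)
  hdr <- grep("^#", lines, value = TRUE)
  kv <- list()
  for (h in hdr) {
    m <- regmatches(h, regexec("^#\\s*([^:]+):\\s*(.*)$", h))[[1]]
    if (length(m) == 3) kv[[trimws(m[2])]] <- trimws(m[3])
  }
  kv$n_header <- length(hdr)
  kv
}

read_trial_body <- function(path, n_header, required, what) {
  df <- read.csv(path, skip = n_header, na.strings = c("", "NA"))
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop(sprintf("%s file %s is missing required column(s): %s",
                 what, path, paste(missing_cols, collapse = ", ")))
  df[required]
}

check_monotone_time <- function(t, path) {
  bad <- which(diff(t) <= 0)
  if (length(bad))
    stop(sprintf("non-monotone timestamps in %s at row(s): %s",
                 path, paste(utils::head(bad + 1, 10), collapse = ", ")))
}

#' Read and write IMU trial files
#'
#' The on-disk dialect is comma-separated with a `#`-prefixed key:value
#' header declaring `trial_id`, `task` and `rate`; columns are `t` (s), `ax,
#' ay, az` (g) and `gx, gy, gz` (deg/s). Reading validates the trial:
#' timestamps must be strictly increasing, accelerations within ±4 g and
#' angular velocities within ±500 deg/s (offending rows are named), and the
#' declared rate must be within 1% of `expected_rate` unless
#' `expected_rate = NULL`. Round-trips are lossless for finite values.
#'
#' @param path File path.
#' @param expected_rate Nominal sampling rate (Hz) the file is checked
#'   against; `NULL` skips the check.
#' @param config Pipeline configuration (sensor ranges).
#' @return `read_imu_trial()` returns an `imu_trial`; `write_imu_trial()`
#'   returns `path` invisibly.
#' @export
read_imu_trial <- function(path, expected_rate = 100, config = default_config()) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- read_trial_header(path)
  if (is.null(hdr$rate)) stop("IMU file ", path, " has no '# rate:' header")
  rate <- as.numeric(hdr$rate)
  if (!is.finite(rate) || rate <= 0) stop("invalid rate in ", path)
  if (!is.null(expected_rate) && abs(rate - expected_rate) > 0.01 * expected_rate)
    warning(sprintf("declared rate %g Hz deviates more than 1%% from the nominal %g Hz",
                    rate, expected_rate))
  df <- read_trial_body(path, hdr$n_header,
                        c("t", "ax", "ay", "az", "gx", "gy", "gz"), "IMU")
  if (anyNA(df))
    stop("malformed rows (missing values) in ", path, " at row(s): ",
         paste(utils::head(which(rowSums(is.na(df)) > 0), 10), collapse = ", "))
  check_monotone_time(df$t, path)
  sim <- config$simulate
  acc_bad <- which(abs(df$ax) > sim$accel_range_g | abs(df$ay) > sim$accel_range_g |
                     abs(df$az) > sim$accel_range_g)
  if (length(acc_bad))
    stop(sprintf("acceleration outside ±%g g in %s at row(s): %s",
                 sim$accel_range_g, path,
                 paste(utils::head(acc_bad, 10), collapse = ", ")))
  gyr_bad <- which(abs(df$gx) > sim$gyro_range_dps | abs(df$gy) > sim$gyro_range_dps |
                     abs(df$gz) > sim$gyro_range_dps)
  if (length(gyr_bad))
    stop(sprintf("angular velocity outside ±%g deg/s in %s at row(s): %s",
                 sim$gyro_range_dps, path,
                 paste(utils::head(gyr_bad, 10), collapse = ", ")))
  new_imu_trial(df, rate = rate,
                task = if (is.null(hdr$task)) NA_character_ else hdr$task,
                trial_id = if (is.null(hdr$trial_id)) basename(path) else hdr$trial_id)
}

#' @rdname read_imu_trial
#' @param trial Trial object to write.
#' @export
write_imu_trial <- function(trial, path) {
  stopifnot(inherits(trial, "imu_trial"))
  write_trial_file(as.data.frame(trial), path, "imu", trial_rate(trial),
                   trial_task(trial), trial_id(trial),
                   "t=s accel=g gyro=deg/s")
}

#' Read and write optical marker trial files
#'
#' Same dialect as [read_imu_trial()] with columns `t` (s) and `x, y, z`
#' (mm). Missing (occluded) frames are empty fields and are read back as
#' `NA`; fill them with [fill_gaps()] before processing.
#'
#' @inheritParams read_imu_trial
#' @return `read_marker_trial()` returns a `marker_trial`;
#'   `write_marker_trial()` returns `path` invisibly.
#' @export
read_marker_trial <- function(path, expected_rate = 200) {
  if (!file.exists(path)) stop("file not found: ", path)
  hdr <- read_trial_header(path)
  if (is.null(hdr$rate)) stop("marker file ", path, " has no '# rate:' header")
  rate <- as.numeric(hdr$rate)
  if (!is.finite(rate) || rate <= 0) stop("invalid rate in ", path)
  if (!is.null(expected_rate) && abs(rate - expected_rate) > 0.01 * expected_rate)
    warning(sprintf("declared rate %g Hz deviates more than 1%% from the nominal %g Hz",
                    rate, expected_rate))
  df <- read_trial_body(path, hdr$n_header, c("t", "x", "y", "z"), "marker")
  if (anyNA(df$t)) stop("missing timestamps in ", path)
  check_monotone_time(df$t, path)
  # occlusion hits all coordinates at once
  miss <- is.na(df$x) | is.na(df$y) | is.na(df$z)
  df$x[miss] <- NA_real_; df$y[miss] <- NA_real_; df$z[miss] <- NA_real_
  new_marker_trial(df, rate = rate,
                   task = if (is.null(hdr$task)) NA_character_ else hdr$task,
                   trial_id = if (is.null(hdr$trial_id)) basename(path) else hdr$trial_id)
}

#' @rdname read_marker_trial
#' @param trial Trial object to write.
#' @export
write_marker_trial <- function(trial, path) {
  stopifnot(inherits(trial, "marker_trial"))
  write_trial_file(as.data.frame(trial), path, "marker", trial_rate(trial),
                   trial_task(trial), trial_id(trial), "t=s pos=mm")
}

#' Fill short marker occlusion gaps by cubic-spline interpolation
#'
#' Every contiguous run of 1-9 missing frames is replaced, per axis, by a
#' cubic interpolating spline through the observed samples. Runs of 10 or
#' more missing frames, and runs touching either end of the trial, make the
#' trial unprocessable and raise an error (condition class
#' `reachkin_gap_error`). Non-missing samples are never altered.
#'
#' @param trial A `marker_trial`.
#' @param max_gap Largest fillable run length (frames); gaps of `max_gap` or
#'   more are errors.
#' @return The trial with all gaps filled.
#' @export
fill_gaps <- function(trial, max_gap = 10) {
  stopifnot(inherits(trial, "marker_trial"))
  miss <- is.na(trial$x)
  if (!any(miss)) return(trial)
  r <- rle(miss)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  gap_runs <- which(r$values)
  too_long <- r$lengths[gap_runs] >= max_gap
  at_edge <- starts[gap_runs] == 1 | ends[gap_runs] == nrow(trial)
  if (any(too_long))
    stop(structure(class = c("reachkin_gap_error", "error", "condition"),
                   list(message = sprintf(
                     "marker gap of %d frames (>= %d) cannot be interpolated",
                     max(r$lengths[gap_runs][too_long]), max_gap),
                     call = sys.call())))
  if (any(at_edge))
    stop(structure(class = c("reachkin_gap_error", "error", "condition"),
                   list(message = "marker gap touches the trial boundary; cannot interpolate",
                        call = sys.call())))
  obs <- !miss
  for (axis in c("x", "y", "z")) {
    f <- splinefun(trial$t[obs], trial[[axis]][obs], method = "fmm")
    trial[[axis]][miss] <- f(trial$t[miss])
  }
  trial
}

# ---- ground-truth sidecars --------------------------------------------------

#' Read / write per-trial ground truth
#'
#' Simulated trials carry a JSON sidecar with the exact movement time, peak
#' velocity, spectral arc length of the noiseless speed profile, and
#' per-segment onset/offset times.
#'
#' @param truth A `ground_truth` object (from [compose_trajectory()]).
#' @param path File path.
#' @return `read_ground_truth()` returns a `ground_truth` list.
#' @export
write_ground_truth <- function(truth, path) {
  stopifnot(inherits(truth, "ground_truth"))
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "ground_truth")
}

# ---- agreement report -------------------------------------------------------

#' Write / read an agreement report
#'
#' The report table (one row per task and metric) is written as plain CSV or
#' as JSON. Numeric round-trips are lossless.
#'
#' @param report An `agreement_report` (see [validate_trials()]).
#' @param path Output path; the extension (`.csv` / `.json`) picks the format
#'   unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @return `read_report()` returns the report data frame.
#' @export
write_report <- function(report, path, format = NULL) {
  if (!inherits(report, "agreement_report"))
    stop("report must be an agreement_report")
  if (nrow(report) == 0)
    stop("refusing to write an empty agreement report: no paired trials were available")
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- as.data.frame(report)
  if (format == "json") {
    jsonlite::write_json(df, path, auto_unbox = TRUE, digits = NA, na = "null")
  } else {
    out <- df
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], function(v) sprintf("%.17g", v))
    write.csv(out, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' @rdname write_report
#' @export
read_report <- function(path, format = NULL) {
  if (is.null(format))
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  df <- if (format == "json") {
    as.data.frame(jsonlite::read_json(path, simplifyVector = TRUE))
  } else {
    read.csv(path)
  }
  structure(df, class = c("agreement_report", "data.frame"))
}
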