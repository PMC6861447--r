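# Trial trimming, stationary detection, and start/center/end sectioning.

no_movement_error <- function(msg) {
  stop(structure(class = c("reachkin_no_movement", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Trim a trial to 100 frames around its significant movement
#'
#' The movement-start predicate is: resultant angular speed > 10 deg/s, OR
#' gravity-compensated earth z-acceleration magnitude > 0.7 g, OR resultant
#' velocity > 0.1 m/s. The movement-end predicate uses the laxer thresholds
#' 5 deg/s / 0.7 g / 0.0025 m/s (setting the sensor down vibrates, so the
#' tail is harder to keep still). The trial is cut 100 frames before the
#' first start-predicate sample and 100 frames after the last end-predicate
#' sample, clamped to the record.
#'
#' @param trial An `imu_trial`.
#' @param velocity_preview Resultant provisional velocity (m/s) per sample,
#'   e.g. an uncorrected integral of earth-frame acceleration.
#' @param earth_accel Optional `earth_accel` matrix for the z-acceleration
#'   criterion; skipped when `NULL`.
#' @param config Pipeline configuration (`trim` group).
#' @return List with 1-based sample indices `trim_start`, `trim_end`
#'   (inclusive).
#' @export
trim_trial <- function(trial, velocity_preview, earth_accel = NULL,
                       config = default_config()) {
  stopifnot(inherits(trial, "imu_trial"))
  n <- nrow(trial)
  if (length(velocity_preview) != n)
    stop("velocity_preview and trial have different lengths")
  tr <- config$trim
  ang <- sqrt(trial$gx^2 + trial$gy^2 + trial$gz^2)
  gz <- if (is.null(earth_accel)) rep(0, n) else
    abs(earth_accel[, 3]) / config$simulate$gravity

  start_pred <- ang > tr$start_gyro_dps | gz > tr$z_accel_g |
    abs(velocity_preview) > tr$start_vel_ms
  end_pred <- ang > tr$end_gyro_dps | gz > tr$z_accel_g |
    abs(velocity_preview) > tr$end_vel_ms

  if (!any(start_pred))
    no_movement_error("no significant movement found: start predicate never satisfied")
  first_mv <- which(start_pred)[1]
  last_mv <- max(which(end_pred))
  list(trim_start = max(1L, first_mv - tr$margin_frames),
       trim_end = min(n, last_mv + tr$margin_frames))
}

#' Detect stationary periods from earth-frame acceleration
#'
#' The resultant gravity-removed acceleration magnitude is passed through a
#' zero-phase (forward-backward) Butterworth high-pass at 0.001 Hz; the
#' absolute value of that output is passed through a zero-phase 2 Hz low-pass
#' Butterworth filter. Samples where this envelope falls below the threshold
#' (default 0.05 g) are marked stationary. Signals are reflection-padded
#' before filtering to suppress edge transients.
#'
#' @param earth_accel An `earth_accel` matrix (m/s^2).
#' @param rate Sampling rate in Hz.
#' @param config Pipeline configuration (`stationary` group).
#' @param angular_speed Optional resultant angular speed (deg/s) per sample:
#'   samples rotating faster than `config$stationary$gyro_veto_dps` are never
#'   stationary, whatever the acceleration envelope says (a slow reach passes
#'   through zero acceleration at peak speed, but the wrist is still
#'   rotating there). `NULL` disables the veto.
#' @return Logical vector, `TRUE` where the sensor is stationary.
#' @export
stationary_mask <- function(earth_accel, rate, config = default_config(),
                            angular_speed = NULL) {
  st <- config$stationary
  mag <- sqrt(rowSums(earth_accel^2))
  n <- length(mag)
  if (n < rate) stop("trial shorter than the filter warm-up (1 s)")
  hp <- signal::butter(st$order, st$highpass_hz / (rate / 2), type = "high")
  lp <- signal::butter(st$order, st$lowpass_hz / (rate / 2), type = "low")
  env <- filtfilt_padded(lp, abs(filtfilt_padded(hp, mag)))
  lo <- st$threshold_g * config$simulate$gravity
  hi <- lo * st$hysteresis_factor
  if (st$hysteresis_factor <= 1) {
    mask <- env < lo
  } else {
    # Schmitt trigger: a stationary sensor is declared moving only once the
    # envelope exceeds hi, and moving becomes stationary only below lo. The
    # zero-phase envelope smears each movement edge outward by ~0.1 s; plain
    # thresholding would start dead reckoning that early and integrate pure
    # noise ahead of the true movement.
    mask <- logical(n)
    state <- env[1] < hi
    for (i in seq_len(n)) {
      if (env[i] > hi) state <- FALSE
      else if (env[i] < lo) state <- TRUE
      mask[i] <- state
    }
  }
  if (!is.null(angular_speed) && st$gyro_veto_dps > 0) {
    if (length(angular_speed) != n)
      stop("angular_speed and earth_accel have different lengths")
    mask <- mask & angular_speed < st$gyro_veto_dps
  }
  # symmetric run-length cleanup: neither rest nor movement can last less
  # than min_run frames - sub-threshold dips at peak speed (acceleration
  # changes sign there) are not rest, and isolated supra-threshold noise
  # blips at rest are not movement
  mask <- drop_short_runs(mask, st$min_run)
  !drop_short_runs(!mask, st$min_run)
}

# A stationary label must persist: isolated sub-threshold dips (the envelope
# crosses zero wherever acceleration changes sign at peak speed) are not
# rest. Runs of TRUE shorter than min_run are relabeled FALSE.
drop_short_runs <- function(mask, min_run) {
  if (min_run <= 1 || !any(mask)) return(mask)
  r <- rle(mask)
  r$values[r$values & r$lengths < min_run] <- FALSE
  inverse.rle(r)
}

# Zero-phase filtering with odd-reflection padding at both ends (the padding
# that scipy/MATLAB filtfilt apply; signal::filtfilt alone leaves large edge
# transients).
filtfilt_padded <- function(filt, x) {
  n <- length(x)
  pad <- min(n - 1, 300)
  left <- 2 * x[1] - x[(pad + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - pad)]
  y <- signal::filtfilt(filt, c(left, x, right))
  y[(pad + 1):(pad + n)]
}

#' Split a trimmed trial into start, center, and end sections
#'
#' The center section runs from the first sample opening a run of at least 10
#' consecutive frames with resultant angular speed above 10 deg/s to the last
#' sample closing a run of at least 20 such frames (the run-length demands
#' make single-frame gyro spikes and set-down vibration inert). Start and
#' end sections lie outside the center and are excluded from peak counting.
#'
#' @param trial A (trimmed) `imu_trial`.
#' @param mask Stationary mask for the same samples (kept for provenance; the
#'   sectioning rule itself is angular-speed based).
#' @param config Pipeline configuration (`sections` group).
#' @return List with 1-based inclusive indices `center_start`, `center_end`.
#' @export
split_sections <- function(trial, mask = NULL, config = default_config()) {
  stopifnot(inherits(trial, "imu_trial"))
  sc <- config$sections
  ang <- sqrt(trial$gx^2 + trial$gy^2 + trial$gz^2)
  hot <- ang > sc$gyro_dps
  r <- rle(hot)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  runs <- which(r$values)
  start_runs <- runs[r$lengths[runs] >= sc$start_run]
  end_runs <- runs[r$lengths[runs] >= sc$end_run]
  if (!length(start_runs) || !length(end_runs))
    no_movement_error(sprintf(
      "no angular-speed run of the required length (>= %d/%d frames above %g deg/s)",
      sc$start_run, sc$end_run, sc$gyro_dps))
  center_start <- starts[start_runs[1]]
  center_end <- ends[end_runs[length(end_runs)]]
  if (center_start >= center_end)
    no_movement_error("degenerate center section")
  list(center_start = center_start, center_end = center_end)
}
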