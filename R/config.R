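#' Default pipeline configuration
#'
#' Returns the full set of tunable constants used across the pipeline, grouped
#' by stage. Every threshold referenced by the processing rules lives here so
#' that a run can be reproduced from the serialized configuration alone.
#'
#' Groups:
#' \describe{
#'   \item{simulate}{Sampling rates (Hz), sensor noise SDs (accelerometer in g,
#'     gyroscope in deg/s, marker in mm), per-axis accelerometer bias SD (g),
#'     stationary lead-in/out (s), inter-trial variability (duration and
#'     amplitude CV, dwell mean/sd in s), scripted wrist-rotation amplitude
#'     (deg), sensor ranges (±4 g, ±500 deg/s), gravity (9.81 m/s^2).}
#'   \item{orientation}{Madgwick filter gain `beta` and the number of leading
#'     frames used to initialize orientation from the mean accelerometer
#'     vector.}
#'   \item{trim}{Movement start/end predicates: angular speed thresholds
#'     (deg/s), gravity-compensated earth z-acceleration threshold (g),
#'     resultant-velocity thresholds (m/s), and the 100-frame margins.}
#'   \item{stationary}{Butterworth high-pass/low-pass cutoffs (Hz), filter
#'     order, and the envelope threshold (g) below which the sensor is
#'     considered stationary.}
#'   \item{sections}{Angular-speed threshold (deg/s) and minimum run lengths
#'     (frames) defining the center section.}
#'   \item{integrate}{ZUPT drift model: "linear" (default) or "none".}
#'   \item{reference}{Predicted mean squared residual (mm^2) targeted by the
#'     marker smoothing spline.}
#'   \item{metrics}{Peak-detection threshold schedule, onset/offset
#'     percentage-of-peak rules and quiet-window lengths (frames), spectral
#'     arc length parameters, and expected peak count per task.}
#' }
#'
#' @return A named nested list.
#' @export
#' @examples
#' cfg <- default_config()
#' cfg$metrics$expected_peaks
default_config <- function() {
  list(
    simulate = list(
      imu_rate = 100,
      marker_rate = 200,
      accel_noise_sd = 0.02,     # g
      gyro_noise_sd = 0.5,       # deg/s
      marker_noise_sd = 0.5,     # mm
      accel_bias_sd = 0.005,     # g, per axis, drawn once per trial
      lead_in = 1.5,             # s stationary before first segment
      lead_out = 1.5,            # s stationary after last segment
      duration_cv = 0.12,
      amplitude_cv = 0.12,
      dwell_sd = 0.1,            # s
      dwell_floor = 0.3,         # s; grasp/release pauses below this are not physiological
      rotation_deg = 15,         # scripted wrist yaw bump per segment
      tremor_per_speed_g = 0,    # optional action-tremor vibration, g per (m/s) of hand speed
      tremor_hz = 9,             # physiological tremor band center
      accel_range_g = 4,
      gyro_range_dps = 500,
      gravity = 9.81
    ),
    orientation = list(
      beta = 0.01,               # rad/s; sqrt(3/4) x mean gyro noise (0.5 deg/s)
      init_window = 100          # frames used for initial orientation
    ),
    trim = list(
      start_gyro_dps = 10,
      end_gyro_dps = 5,
      z_accel_g = 0.7,
      start_vel_ms = 0.1,
      end_vel_ms = 0.0025,
      margin_frames = 100
    ),
    stationary = list(
      highpass_hz = 0.001,
      lowpass_hz = 2,
      order = 2,
      threshold_g = 0.05,
      hysteresis_factor = 1,     # >1: leave "stationary" only above factor x threshold
      min_run = 10,              # frames; shorter stationary/moving runs are relabeled
      gyro_veto_dps = 10         # a sample rotating faster than this is never stationary
    ),
    sections = list(
      gyro_dps = 10,
      start_run = 10,
      end_run = 20
    ),
    integrate = list(
      drift_model = "linear"
    ),
    reference = list(
      target_mse_mm2 = 5
    ),
    metrics = list(
      peak_threshold_init = 0.1,   # m/s
      peak_threshold_factor = 1.05,
      peak_max_iter = 60,
      onset_pct_imu = 0.01,
      onset_pct_reference = 0.02,
      offset_pct = 0.02,
      onset_window_frames = 50,
      offset_window_frames = 75,
      quiet_velocity_ms = 0.05,
      sparc_freq_cutoff = 20,      # Hz
      sparc_amp_threshold = 0.05,
      sparc_pad_factor = 16,
      expected_peaks = c(block = 3, drink = 3, pour = 4)
    )
  )
}

#' Read / write a pipeline configuration
#'
#' Configurations are stored as YAML so that a processing run can be repeated
#' from the file alone. Missing groups or entries are filled from
#' [default_config()].
#'
#' @param path File path.
#' @param config Configuration list as returned by [default_config()].
#' @return `read_config()` returns a complete configuration list;
#'   `write_config()` returns `path` invisibly.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  user <- yaml::read_yaml(path)
  merge_config(default_config(), user)
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  # YAML drops names on the expected_peaks vector unless stored as a map
  config$metrics$expected_peaks <- as.list(config$metrics$expected_peaks)
  yaml::write_yaml(config, path)
  invisible(path)
}

merge_config <- function(base, user) {
  if (is.null(user)) return(base)
  for (nm in names(user)) {
    if (is.list(base[[nm]]) && is.list(user[[nm]]) && nm != "expected_peaks") {
      base[[nm]] <- merge_config(base[[nm]], user[[nm]])
    } else if (nm == "expected_peaks") {
      base[[nm]] <- unlist(user[[nm]])
    } else {
      base[[nm]] <- user[[nm]]
    }
  }
  base
}

expected_peaks_for <- function(task, config = default_config()) {
  ep <- config$metrics$expected_peaks
  if (!task %in% names(ep)) stop("unknown task: ", task)
  unname(ep[[task]])
}

reachkin_tasks <- function() c("block", "drink", "pour")
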