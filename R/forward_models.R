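#' Simulate the wrist IMU from a composed trajectory
#'
#' Evaluates the trajectory analytically at the IMU sampling rate and maps it
#' through the sensor model: the specific force (linear acceleration plus
#' gravity) is rotated into the sensor frame by the inverse of the scripted
#' orientation, converted to g, and corrupted with the spec's per-axis bias
#' and seeded Gaussian noise; angular velocity (deg/s) receives seeded noise.
#' Values are clipped to the device ranges (±4 g, ±500 deg/s). Two calls with
#' the same spec produce bit-identical output.
#'
#' @param trajectory A [compose_trajectory()] result.
#' @param spec The [trial_spec()] (defaults to the one inside `trajectory`).
#' @param config Pipeline configuration (sensor ranges, gravity).
#' @return An `imu_trial` object: data frame `t, ax, ay, az, gx, gy, gz` with
#'   attributes `rate`, `task`, `trial_id`.
#' @export
imu_forward_model <- function(trajectory, spec = trajectory$spec,
                              config = default_config()) {
  stopifnot(inherits(trajectory, "reach_trajectory"))
  sim <- config$simulate
  g <- sim$gravity
  t <- seq(0, trajectory$total_time, by = 1 / spec$imu_rate)
  kin <- eval_trajectory(trajectory$segments, t)
  yaw <- eval_yaw(trajectory$segments, t, spec$rotation_deg)

  max_rate <- max(abs(yaw$rate))
  if (max_rate > sim$gyro_range_dps)
    warning(sprintf("scripted rotation rate %.0f deg/s exceeds the ±%.0f deg/s range; clipped",
                    max_rate, sim$gyro_range_dps))

  # orientation: sensor pronated (sensor z up), plus scripted yaw about earth z
  half <- yaw$angle * pi / 180 / 2
  Q <- cbind(cos(half), 0, 0, sin(half))          # sensor -> earth
  Qinv <- cbind(Q[, 1], 0, 0, -Q[, 4])
  specific <- kin$acc + tremor_acceleration(t, kin$vel, spec, sim)
  specific[, 3] <- specific[, 3] + g
  accel_s <- quat_rotate_rows(Qinv, specific) / g  # in g

  # yaw about earth z is yaw about sensor z for this orientation family
  gyro_s <- cbind(0, 0, yaw$rate)

  n <- length(t)
  noise <- with_seed(spec$seed + 101L, {
    list(a = matrix(rnorm(3 * n, 0, spec$accel_noise_sd), n, 3),
         g = matrix(rnorm(3 * n, 0, spec$gyro_noise_sd), n, 3))
  })
  accel <- sweep(accel_s + noise$a, 2, spec$accel_bias, `+`)
  gyro <- gyro_s + noise$g
  accel <- pmin(pmax(accel, -sim$accel_range_g), sim$accel_range_g)
  gyro <- pmin(pmax(gyro, -sim$gyro_range_dps), sim$gyro_range_dps)

  new_imu_trial(data.frame(t = t,
                           ax = accel[, 1], ay = accel[, 2], az = accel[, 3],
                           gx = gyro[, 1], gy = gyro[, 2], gz = gyro[, 3]),
                rate = spec$imu_rate, task = spec$task, trial_id = spec$trial_id)
}

# Physiological action tremor: a narrowband (default 9 Hz) oscillation whose
# amplitude scales with hand speed, shared by both forward models (it is real
# micro-motion of the hand, seen by the accelerometer and - as a ~0.4 mm
# position ripple - by the optical marker). Real wrist recordings never show
# a clean zero-acceleration envelope mid-reach; without this component the
# idealized minimum-jerk profile would fool the acceleration-envelope
# stationary detector exactly at each segment's peak-speed instant. The
# tremor is excluded from the ground truth (it is superimposed physiological
# noise, not task kinematics). Returns an n x 3 acceleration in m/s^2.
tremor_acceleration <- function(t, vel, spec, sim) {
  if (sim$tremor_per_speed_g <= 0) return(matrix(0, length(t), 3))
  pars <- with_seed(spec$seed + 303L,
                    list(dir = rnorm(3), phase = runif(1, 0, 2 * pi)))
  u <- pars$dir / sqrt(sum(pars$dir^2))
  speed <- sqrt(rowSums(vel^2))
  amp <- sim$tremor_per_speed_g * sim$gravity * speed *
    sin(2 * pi * sim$tremor_hz * t + pars$phase)
  outer(amp, u)
}

#' Simulate the optical wrist marker from a composed trajectory
#'
#' Evaluates the trajectory at the marker sampling rate, converts to mm, adds
#' seeded Gaussian marker noise, and optionally blanks short runs of frames to
#' emulate occlusion gaps. Gaps of 10 or more frames are refused (such trials
#' are unprocessable downstream; the gap-filling rule only covers shorter
#' gaps).
#'
#' @inheritParams imu_forward_model
#' @param gaps Optional list of `c(start_frame, length)` pairs; each blanks
#'   `length` (< 10) consecutive frames starting at `start_frame`.
#' @return A `marker_trial` object: data frame `t, x, y, z` (mm, `NA` in
#'   gaps) with attributes `rate`, `task`, `trial_id`.
#' @export
marker_forward_model <- function(trajectory, spec = trajectory$spec,
                                 gaps = NULL, config = default_config()) {
  stopifnot(inherits(trajectory, "reach_trajectory"))
  sim <- config$simulate
  t <- seq(0, trajectory$total_time, by = 1 / spec$marker_rate)
  kin <- eval_trajectory(trajectory$segments, t)
  # tremor displacement consistent with the IMU model's tremor acceleration:
  # for a narrowband oscillation, x(t) ~ -a(t) / omega^2
  omega <- 2 * pi * sim$tremor_hz
  pos_mm <- (kin$pos - tremor_acceleration(t, kin$vel, spec, sim) / omega^2) * 1000
  n <- length(t)
  noise <- with_seed(spec$seed + 202L,
                     matrix(rnorm(3 * n, 0, spec$marker_noise_sd), n, 3))
  pos_mm <- pos_mm + noise
  if (!is.null(gaps)) {
    for (gp in gaps) {
      if (length(gp) != 2) stop("each gap must be c(start_frame, length)")
      if (gp[2] >= 10)
        stop("gap length ", gp[2], " >= 10 frames: only gaps of < 10 frames are supported")
      idx <- gp[1]:(gp[1] + gp[2] - 1)
      if (any(idx < 1 | idx > n)) stop("gap outside trial")
      pos_mm[idx, ] <- NA_real_
    }
  }
  new_marker_trial(data.frame(t = t, x = pos_mm[, 1], y = pos_mm[, 2],
                              z = pos_mm[, 3]),
                   rate = spec$marker_rate, task = spec$task,
                   trial_id = spec$trial_id)
}
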