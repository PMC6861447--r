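#' Madgwick attitude filter (IMU variant, no magnetometer)
#'
#' Estimates the per-sample sensor orientation by integrating the gyroscope
#' quaternion rate and correcting it towards the accelerometer's gravity
#' direction with Madgwick's normalized gradient-descent step, scaled by the
#' gain `beta` (rad/s). Quaternions map sensor-frame vectors into the earth
#' frame, `v_e = q v_s q*`, and are re-normalized every step. A zero-norm
#' accelerometer sample skips the correction for that step. Heading (yaw) is
#' unobservable without a magnetometer; all downstream metrics are
#' resultant-magnitude based, so heading drift is irrelevant.
#'
#' The initial orientation is taken from the mean accelerometer vector over
#' the first `init_window` frames (the trial protocol guarantees a stationary
#' lead-in), with yaw set to zero; pass `q0` to override.
#'
#' @param trial An `imu_trial`.
#' @param beta Filter gain in rad/s (>= 0). `beta = 0` is pure gyro
#'   integration.
#' @param q0 Optional initial unit quaternion `(w, x, y, z)`.
#' @param config Pipeline configuration (`orientation` group).
#' @return A `quaternion_series`: n x 4 matrix with attributes `beta`, `t`.
#' @export
ahrs_filter <- function(trial, beta = NULL, q0 = NULL,
                        config = default_config()) {
  stopifnot(inherits(trial, "imu_trial"))
  if (is.null(beta)) beta <- config$orientation$beta
  if (beta < 0) stop("beta must be >= 0")
  n <- nrow(trial)
  if (n < 2) stop("trial too short for orientation filtering")

  acc <- cbind(trial$ax, trial$ay, trial$az)
  gyr <- cbind(trial$gx, trial$gy, trial$gz) * pi / 180
  t <- trial$t

  if (is.null(q0)) q0 <- initial_orientation(trial, config)
  q <- quat_normalize(q0)
  Q <- matrix(0, n, 4)
  Q[1, ] <- q

  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
    gx <- gyr[i, 1]; gy <- gyr[i, 2]; gz <- gyr[i, 3]
    # quaternion rate from gyro: 0.5 * q x (0, omega)
    qd1 <- 0.5 * (-x * gx - y * gy - z * gz)
    qd2 <- 0.5 * (w * gx + y * gz - z * gy)
    qd3 <- 0.5 * (w * gy - x * gz + z * gx)
    qd4 <- 0.5 * (w * gz + x * gy - y * gx)
    an <- sqrt(sum(acc[i, ]^2))
    if (beta > 0 && an > 0) {
      ax <- acc[i, 1] / an; ay <- acc[i, 2] / an; az <- acc[i, 3] / an
      # objective: predicted gravity in the sensor frame minus measurement
      f1 <- 2 * (x * z - w * y) - ax
      f2 <- 2 * (w * x + y * z) - ay
      f3 <- 2 * (0.5 - x * x - y * y) - az
      s1 <- -2 * y * f1 + 2 * x * f2
      s2 <-  2 * z * f1 + 2 * w * f2 - 4 * x * f3
      s3 <- -2 * w * f1 + 2 * z * f2 - 4 * y * f3
      s4 <-  2 * x * f1 + 2 * y * f2
      # skip the normalized step when the gradient is numerically zero
      # (normalizing rounding noise would give a full-size step in an
      # arbitrary direction at the equilibrium)
      sn <- sqrt(s1 * s1 + s2 * s2 + s3 * s3 + s4 * s4)
      if (sn > 1e-12) {
        qd1 <- qd1 - beta * s1 / sn
        qd2 <- qd2 - beta * s2 / sn
        qd3 <- qd3 - beta * s3 / sn
        qd4 <- qd4 - beta * s4 / sn
      }
    }
    q <- c(w + qd1 * dt, x + qd2 * dt, y + qd3 * dt, z + qd4 * dt)
    q <- q / sqrt(sum(q * q))
    Q[i, ] <- q
  }
  structure(Q, beta = beta, t = t, class = c("quaternion_series", "matrix", "array"))
}

# Orientation whose rotation takes the measured mean gravity direction onto
# earth up; yaw fixed at zero.
initial_orientation <- function(trial, config = default_config()) {
  w <- min(nrow(trial), config$orientation$init_window)
  a <- colMeans(cbind(trial$ax[1:w], trial$ay[1:w], trial$az[1:w]))
  if (sqrt(sum(a^2)) == 0) return(c(1, 0, 0, 0))
  quat_between(a, c(0, 0, 1))
}

#' Rotate accelerometer data to the earth frame and remove gravity
#'
#' Rotates each accelerometer sample by its orientation quaternion, subtracts
#' 1 g from the earth z axis, and converts to m/s^2. For a static noiseless
#' trial with converged orientation the result is the zero vector, whatever
#' the sensor's attitude.
#'
#' @param trial An `imu_trial`.
#' @param q A `quaternion_series` from [ahrs_filter()], aligned
#'   sample-for-sample with `trial`.
#' @param gravity Gravitational acceleration (m/s^2).
#' @return An `earth_accel`: n x 3 matrix (m/s^2) with attribute `t`.
#' @export
to_earth_frame <- function(trial, q, gravity = 9.81) {
  stopifnot(inherits(trial, "imu_trial"))
  if (nrow(q) != nrow(trial))
    stop("orientation series and trial have different lengths")
  a_e <- quat_rotate_rows(q, cbind(trial$ax, trial$ay, trial$az)) * gravity
  a_e[, 3] <- a_e[, 3] - gravity
  structure(a_e, t = trial$t, class = c("earth_accel", "matrix", "array"))
}
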