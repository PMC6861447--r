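#' Minimum-jerk point-to-point kinematics
#'
#' Position, velocity and acceleration of the quintic minimum-jerk profile
#' `x(t) = A (10 tau^3 - 15 tau^4 + 6 tau^5)`, `tau = t / T`, the standard
#' model of smooth point-to-point reaching. Velocity and acceleration vanish
#' at both endpoints; peak speed is `1.875 A / T` at the midpoint.
#'
#' @param amplitude Total displacement (m, or any length unit).
#' @param duration Movement duration `T` in seconds (> 0).
#' @param t Time since movement onset, vectorized; must lie in `[0, duration]`.
#' @return Numeric vector of the same length as `t`.
#' @export
#' @examples
#' minimum_jerk_position(0.25, 1, 0.5)   # 0.125, midpoint symmetry
#' minimum_jerk_velocity(0.25, 1, 0.5)   # 0.46875 = 1.875 * 0.25 / 1
minimum_jerk_position <- function(amplitude, duration, t) {
  check_mj_args(duration, t)
  tau <- t / duration
  amplitude * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
}

#' @rdname minimum_jerk_position
#' @export
minimum_jerk_velocity <- function(amplitude, duration, t) {
  check_mj_args(duration, t)
  tau <- t / duration
  amplitude / duration * (30 * tau^2 - 60 * tau^3 + 30 * tau^4)
}

#' @rdname minimum_jerk_position
#' @export
minimum_jerk_acceleration <- function(amplitude, duration, t) {
  check_mj_args(duration, t)
  tau <- t / duration
  amplitude / duration^2 * (60 * tau - 180 * tau^2 + 120 * tau^3)
}

check_mj_args <- function(duration, t) {
  if (!is.numeric(duration) || length(duration) != 1 || duration <= 0)
    stop("duration must be a positive scalar")
  if (any(t < -1e-12) || any(t > duration + 1e-12))
    stop("t outside [0, duration]")
  invisible(TRUE)
}

# Peak speed of a minimum-jerk segment (closed form).
minimum_jerk_peak_speed <- function(amplitude, duration) {
  1.875 * abs(amplitude) / duration
}
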