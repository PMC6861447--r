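#' ZUPT dead reckoning: drift-corrected resultant velocity
#'
#' Integrates earth-frame acceleration per axis (trapezoidal rule, time steps
#' from the timestamp vector) within each non-stationary interval bounded by
#' stationary samples. Because velocity must return to zero at the end of
#' each interval, the residual end velocity is removed by subtracting a drift
#' ramp that grows linearly in time from zero at the interval start to the
#' residual at the interval end (the standard zero-velocity-update
#' assumption). Velocity is pinned to exactly zero on stationary samples,
#' and correction is applied per axis before taking the Euclidean norm
#' (norm-then-correct would bias speed upward).
#'
#' @param earth_accel An `earth_accel` matrix (m/s^2) with a `t` attribute,
#'   or a plain matrix plus `t`.
#' @param mask Logical stationary mask, aligned with `earth_accel`.
#' @param rate Sampling rate in Hz.
#' @param t Optional timestamp vector; defaults to the `t` attribute of
#'   `earth_accel`.
#' @param drift One of `"linear"` (default, ZUPT ramp) or `"none"` (plain
#'   integration; for ablation).
#' @param source Provenance label of the resulting profile.
#' @return A `velocity_profile`: list with resultant speed `v` (m/s),
#'   per-axis velocity `v_axes`, timestamps `t`, `rate`, `source`.
#' @export
integrate_velocity <- function(earth_accel, mask, rate, t = NULL,
                               drift = c("linear", "none"), source = "imu") {
  drift <- match.arg(drift)
  if (is.null(t)) t <- attr(earth_accel, "t")
  if (is.null(t)) stop("timestamps required: supply t or an earth_accel with a t attribute")
  n <- nrow(earth_accel)
  if (length(mask) != n || length(t) != n)
    stop("earth_accel, mask and t must be aligned")

  v <- matrix(0, n, 3)
  r <- rle(!mask)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  for (j in which(r$values)) {
    i0 <- starts[j]; i1 <- ends[j]
    if (i0 == 1 || i1 == n)
      stop(structure(class = c("reachkin_unbounded_movement", "error", "condition"),
                     list(message = "movement interval not bounded by stationary samples (trial starts or ends mid-movement)",
                          call = sys.call())))
    idx <- (i0 - 1):(i1 + 1)
    tseg <- t[idx]
    vseg <- pracma::cumtrapz(tseg, earth_accel[idx, , drop = FALSE])
    if (drift == "linear") {
      frac <- (tseg - tseg[1]) / (tseg[length(tseg)] - tseg[1])
      vseg <- vseg - outer(frac, vseg[length(tseg), ])
    }
    v[idx, ] <- vseg
  }
  v[mask, ] <- 0
  speed <- sqrt(rowSums(v^2))
  new_velocity_profile(speed, t, rate, source, v_axes = v)
}

new_velocity_profile <- function(v, t, rate, source, v_axes = NULL) {
  structure(list(v = v, t = t, rate = rate, source = source, v_axes = v_axes),
            class = "velocity_profile")
}

#' @export
print.velocity_profile <- function(x, ...) {
  cat(sprintf("<velocity_profile> source=%s n=%d rate=%g Hz, max %.3f m/s\n",
              x$source, length(x$v), x$rate, max(x$v)))
  invisible(x)
}

#' @export
plot.velocity_profile <- function(x, ...) {
  graphics::plot(x$t, x$v, type = "l", xlab = "time (s)",
                 ylab = "resultant velocity (m/s)",
                 main = sprintf("%s velocity profile", x$source), ...)
  invisible(x)
}

# Provisional (uncorrected) resultant velocity over the full record, used
# only inside the trim predicates: per-axis running integral of earth-frame
# acceleration without any stationarity information.
provisional_velocity <- function(earth_accel, t = attr(earth_accel, "t")) {
  v <- pracma::cumtrapz(t, earth_accel)
  sqrt(rowSums(v^2))
}
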