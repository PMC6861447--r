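# Reference (optical marker) pipeline: predicted-MSE smoothing, central
# difference velocity, and alignment to the IMU window.

#' Smooth marker trajectories to a target residual MSE
#'
#' Per-axis cubic smoothing spline whose penalty is solved (by root finding
#' on log lambda) so that the mean squared residual to the raw samples equals
#' `target_mse` within 5%. This reproduces the predicted-MSE parameterization
#' of the Woltring smoother used by optical-capture pipelines: the residual
#' left in the data is told to match the assumed measurement error. When the
#' data are cleaner than the requested MSE (the target exceeds the noise
#' variance estimated from second differences), reaching the target would
#' distort the signal, so smoothing is capped at the estimated noise variance
#' and a warning is raised.
#'
#' @param trial A gap-free `marker_trial` (run [fill_gaps()] first).
#' @param target_mse Predicted mean squared residual in mm^2 (default 5).
#' @param config Pipeline configuration.
#' @return The trial with smoothed `x`, `y`, `z`.
#' @export
smooth_markers <- function(trial, target_mse = NULL, config = default_config()) {
  stopifnot(inherits(trial, "marker_trial"))
  if (anyNA(trial$x)) stop("marker trial has unfilled gaps; run fill_gaps() first")
  if (is.null(target_mse)) target_mse <- config$reference$target_mse_mm2
  n <- nrow(trial)
  if (n < 10) stop("too few samples to smooth")

  sigma2 <- mean(vapply(c("x", "y", "z"), function(a)
    mean(diff(trial[[a]], differences = 2)^2) / 6, 0))
  eff_target <- target_mse
  if (sigma2 < target_mse) {
    eff_target <- sigma2
    warning(sprintf(
      "target MSE %.3g mm^2 exceeds the estimated noise variance %.3g mm^2; smoothing capped",
      target_mse, sigma2))
  }

  for (axis in c("x", "y", "z")) {
    trial[[axis]] <- mse_targeted_spline(trial$t, trial[[axis]], eff_target)
  }
  trial
}

# Quintic penalized B-spline smoother (third-derivative penalty, the
# Woltring choice for trajectories that will be differentiated: at equal
# residual it rolls off high frequencies much harder than a cubic smoother
# and preserves peaks better). The penalty weight is solved so the residual
# MSE matches the target; MSE is monotone increasing in lambda. Basis and
# Gram matrices are built once, so the lambda search costs only k x k solves.
mse_targeted_spline <- function(t, x, target, knots_per_s = 50) {
  n <- length(t)
  span <- diff(range(t))
  k_int <- max(20, min(n %/% 4, ceiling(span * knots_per_s)))
  ord <- 6  # quintic
  inner <- seq(min(t), max(t), length.out = k_int)
  knots <- c(rep(min(t), ord - 1), inner, rep(max(t), ord - 1))
  B <- splines::splineDesign(knots, t, ord = ord)
  # third-derivative penalty by quadrature on a fine grid
  tg <- seq(min(t), max(t), length.out = 4 * k_int)
  D3 <- splines::splineDesign(knots, tg, ord = ord, derivs = rep(3, length(tg)))
  S <- crossprod(D3) * (tg[2] - tg[1])
  S <- S / mean(diag(S))  # scale-free penalty so the lambda grid is bounded
  BtB <- crossprod(B)
  Btx <- crossprod(B, x)
  fit_for <- function(lambda) {
    R <- chol(BtB + lambda * S)
    beta <- backsolve(R, forwardsolve(t(R), Btx))
    drop(B %*% beta)
  }
  mse_for <- function(ll) mean((fit_for(10^ll) - x)^2)
  lo <- -12; hi <- 10
  if (target <= mse_for(lo)) return(fit_for(10^lo))
  if (target >= mse_for(hi)) return(fit_for(10^hi))
  root <- stats::uniroot(function(ll) mse_for(ll) - target, c(lo, hi),
                         tol = 0.01)$root
  fit_for(10^root)
}

#' Central-difference velocity from marker positions
#'
#' First-order central differences per axis,
#' `v_i = (p_{i+1} - p_{i-1}) / (2 dt)`, one-sided at the ends (exact for
#' quadratic position tracks); positions in mm are converted to m and the
#' resultant Euclidean norm is returned.
#'
#' @param trial A smoothed, gap-free `marker_trial`.
#' @return A `velocity_profile` with `source = "reference"`.
#' @export
differentiate <- function(trial) {
  stopifnot(inherits(trial, "marker_trial"))
  n <- nrow(trial)
  if (n < 3) stop("need at least 3 samples to differentiate")
  if (anyNA(trial$x)) stop("marker trial has unfilled gaps")
  t <- trial$t
  v <- sapply(c("x", "y", "z"), function(axis) {
    p <- trial[[axis]] / 1000  # mm -> m
    c((p[2] - p[1]) / (t[2] - t[1]),
      (p[3:n] - p[1:(n - 2)]) / (t[3:n] - t[1:(n - 2)]),
      (p[n] - p[n - 1]) / (t[n] - t[n - 1]))
  })
  new_velocity_profile(sqrt(rowSums(v^2)), t, trial_rate(trial),
                       "reference", v_axes = v)
}

#' Crop the reference profile to the IMU's trimmed time window
#'
#' Trials from the two systems share a common start clock but different
#' rates, so the crop is by time, not index. Windows extending past the
#' reference record are clamped with a warning; a window with no overlap is
#' an error.
#'
#' @param ref A reference `velocity_profile`.
#' @param window Numeric `c(t0, t1)` in seconds (the IMU trim window).
#' @return The cropped `velocity_profile`.
#' @export
align_to_imu <- function(ref, window) {
  stopifnot(inherits(ref, "velocity_profile"), length(window) == 2)
  t0 <- window[1]; t1 <- window[2]
  if (t1 <= t0) stop("invalid window")
  if (t0 > ref$t[length(ref$t)] || t1 < ref$t[1])
    stop("IMU window does not overlap the reference recording")
  if (t0 < ref$t[1] - 1e-9 || t1 > ref$t[length(ref$t)] + 1e-9)
    warning("IMU window extends past the reference recording; clamped")
  eps <- 1e-9
  keep <- ref$t >= t0 - eps & ref$t <= t1 + eps
  new_velocity_profile(ref$v[keep], ref$t[keep], ref$rate, ref$source,
                       v_axes = ref$v_axes[keep, , drop = FALSE])
}
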