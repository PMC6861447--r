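#' Compose a full trial trajectory from a specification
#'
#' Concatenates the spec's minimum-jerk segments with their exact dwells and
#' stationary lead-in/out, and evaluates position, velocity and acceleration
#' analytically on a regular grid. Also evaluates the scripted wrist yaw
#' (one smooth 0 -> A -> 0 rotation bump per segment) and assembles the
#' trial's ground truth: movement time, peak velocity (closed form
#' `1.875 |A| / T` over segments), per-segment onset/offset times, and the
#' spectral arc length of the noiseless speed profile sampled at the IMU rate
#' over the movement window.
#'
#' @param spec A [trial_spec()].
#' @param rate Evaluation grid rate in Hz (default 1000; the forward models
#'   re-evaluate analytically at their own sensor rates).
#' @return A `reach_trajectory` list with elements `time`, `pos`, `vel`, `acc`
#'   (n x 3, m / m s^-1 / m s^-2), `yaw_deg`, `yaw_rate_dps`, `segments`
#'   (table of absolute onset/offset times and geometry), `total_time`, and
#'   `truth` (a `ground_truth` list).
#' @export
#' @examples
#' spec <- trial_spec("block", list(
#'   segment_spec(c(0.25, 0, 0), 1, 0.5),
#'   segment_spec(c(0, 0.25, 0), 1, 0.5),
#'   segment_spec(c(-0.25, -0.25, 0), 1)), seed = 1)
#' traj <- compose_trajectory(spec)
#' traj$truth$peak_velocity   # 0.46875 = 1.875 * 0.25 / 1
compose_trajectory <- function(spec, rate = 1000) {
  stopifnot(inherits(spec, "trial_spec"))
  seg <- segment_table(spec)
  total_time <- spec$lead_in + sum(seg$duration) +
    sum(vapply(spec$segments, `[[`, 0, "dwell_after")) + spec$lead_out
  # the trailing dwell of the last segment is folded into lead_out
  total_time <- seg$t_off[nrow(seg)] +
    spec$segments[[length(spec$segments)]]$dwell_after + spec$lead_out

  time <- seq(0, total_time, by = 1 / rate)
  kin <- eval_trajectory(seg, time)
  yaw <- eval_yaw(seg, time, spec$rotation_deg)

  truth <- ground_truth(spec, seg)
  structure(list(time = time, pos = kin$pos, vel = kin$vel, acc = kin$acc,
                 yaw_deg = yaw$angle, yaw_rate_dps = yaw$rate,
                 segments = seg, total_time = total_time,
                 truth = truth, spec = spec),
            class = "reach_trajectory")
}

# Absolute timing and geometry of each segment.
segment_table <- function(spec) {
  n <- length(spec$segments)
  t_on <- numeric(n); t_off <- numeric(n)
  t <- spec$lead_in
  for (i in seq_len(n)) {
    t_on[i] <- t
    t_off[i] <- t + spec$segments[[i]]$duration
    t <- t_off[i] + spec$segments[[i]]$dwell_after
  }
  amp <- t(vapply(spec$segments, `[[`, numeric(3), "amplitude"))
  data.frame(t_on = t_on, t_off = t_off,
             duration = t_off - t_on,
             ax = amp[, 1], ay = amp[, 2], az = amp[, 3],
             norm = sqrt(rowSums(amp^2)))
}

# Vectorized analytic evaluation of the composed trajectory at times `t`.
eval_trajectory <- function(seg, t) {
  n <- length(t)
  pos <- matrix(0, n, 3); vel <- matrix(0, n, 3); acc <- matrix(0, n, 3)
  for (i in seq_len(nrow(seg))) {
    amp <- c(seg$ax[i], seg$ay[i], seg$az[i])
    after <- t >= seg$t_off[i]
    within <- t >= seg$t_on[i] & !after
    if (any(after)) pos[after, ] <- sweep(pos[after, , drop = FALSE], 2, amp, `+`)
    if (any(within)) {
      tt <- t[within] - seg$t_on[i]
      for (k in 1:3) {
        if (amp[k] == 0) next
        pos[within, k] <- pos[within, k] +
          minimum_jerk_position(amp[k], seg$duration[i], tt)
        vel[within, k] <- vel[within, k] +
          minimum_jerk_velocity(amp[k], seg$duration[i], tt)
        acc[within, k] <- acc[within, k] +
          minimum_jerk_acceleration(amp[k], seg$duration[i], tt)
      }
    }
  }
  list(pos = pos, vel = vel, acc = acc)
}

# Scripted wrist yaw: each segment carries one monotone minimum-jerk wrist
# rotation of `rotation_deg`, alternating in sign from segment to segment
# (reach with slight supination, return with pronation). The rotation rate
# therefore peaks mid-segment - exactly where translational acceleration
# crosses zero - so the gyroscope unambiguously signals movement throughout
# each segment, as it does on a real wrist.
eval_yaw <- function(seg, t, rotation_deg) {
  angle <- numeric(length(t)); rate <- numeric(length(t))
  if (rotation_deg == 0) return(list(angle = angle, rate = rate))
  for (i in seq_len(nrow(seg))) {
    amp <- rotation_deg * (-1)^(i + 1)
    after <- t >= seg$t_off[i]
    within <- t >= seg$t_on[i] & !after
    angle[after] <- angle[after] + amp
    if (any(within)) {
      tt <- t[within] - seg$t_on[i]
      angle[within] <- angle[within] +
        minimum_jerk_position(amp, seg$duration[i], tt)
      rate[within] <- minimum_jerk_velocity(amp, seg$duration[i], tt)
    }
  }
  list(angle = angle, rate = rate)
}

# Exact per-trial ground truth derived from the spec alone.
ground_truth <- function(spec, seg = segment_table(spec)) {
  peak_velocity <- max(minimum_jerk_peak_speed(seg$norm, seg$duration))
  movement_time_ms <- (seg$t_off[nrow(seg)] - seg$t_on[1]) * 1000

  # reference value of the smoothness metric: noiseless speed sampled at the
  # IMU rate over the movement window
  tt <- seq(seg$t_on[1], seg$t_off[nrow(seg)], by = 1 / spec$imu_rate)
  speed <- sqrt(rowSums(eval_trajectory(seg, tt)$vel^2))
  sparc_true <- sparc(speed, spec$imu_rate)

  structure(list(movement_time_ms = movement_time_ms,
                 peak_velocity = peak_velocity,
                 sparc_true = sparc_true,
                 seg_onsets = seg$t_on, seg_offsets = seg$t_off,
                 task = spec$task, trial_id = spec$trial_id,
                 seed = spec$seed),
            class = "ground_truth")
}

#' @export
print.reach_trajectory <- function(x, ...) {
  cat(sprintf("<reach_trajectory> task=%s n=%d (%.2f s), peak speed %.3f m/s\n",
              x$spec$task, length(x$time), x$total_time, x$truth$peak_velocity))
  invisible(x)
}
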