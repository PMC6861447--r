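# Shared fixture builders. Everything is generated in code; no stored data.

make_imu_trial <- function(t, ax = 0, ay = 0, az = 1, gx = 0, gy = 0, gz = 0,
                           rate = 100, task = "block", id = "fixture") {
  n <- length(t)
  reachkin:::new_imu_trial(
    data.frame(t = t,
               ax = rep_len(ax, n), ay = rep_len(ay, n), az = rep_len(az, n),
               gx = rep_len(gx, n), gy = rep_len(gy, n), gz = rep_len(gz, n)),
    rate = rate, task = task, trial_id = id)
}

make_marker_trial <- function(t, x, y = 0, z = 0, rate = 200,
                              task = "block", id = "fixture") {
  n <- length(t)
  reachkin:::new_marker_trial(
    data.frame(t = t, x = rep_len(x, n), y = rep_len(y, n), z = rep_len(z, n)),
    rate = rate, task = task, trial_id = id)
}

# a small, fast block spec with explicit geometry (no jitter)
fixed_block_spec <- function(seed = 1, dwell = 0.5, ...) {
  trial_spec("block", list(
    segment_spec(c(0.15, 0, 0), 0.8, dwell),
    segment_spec(c(0.10, 0, 0.37), 0.9, dwell),
    segment_spec(c(-0.25, 0, -0.37), 0.9)),
    seed = seed, ...)
}

# exhaustive strict local-maximum scan (independent peak oracle for clean
# profiles)
neighbor_scan_peaks <- function(v, threshold = -Inf) {
  idx <- which(v[2:(length(v) - 1)] > v[1:(length(v) - 2)] &
                 v[2:(length(v) - 1)] > v[3:length(v)]) + 1
  idx[v[idx] > threshold]
}
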