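#' Simulate one paired IMU + marker trial
#'
#' Draws a randomized specification for the task, composes the trajectory and
#' runs both forward models. Everything is a pure function of `(task, seed,
#' config)`.
#'
#' @param task Task label (`"block"`, `"drink"`, `"pour"`).
#' @param seed Integer seed (required).
#' @param config Pipeline configuration.
#' @param trial_id Identifier string.
#' @return List with `imu` (`imu_trial`), `marker` (`marker_trial`),
#'   `truth` (`ground_truth`), `spec` (`trial_spec`).
#' @export
#' @examples
#' tr <- simulate_trial("block", seed = 7)
#' tr$truth$peak_velocity
simulate_trial <- function(task, seed, config = default_config(),
                           trial_id = sprintf("%s-%06d", task, seed)) {
  spec <- draw_trial_spec(task, seed, config, trial_id)
  traj <- compose_trajectory(spec)
  list(imu = imu_forward_model(traj, spec, config),
       marker = marker_forward_model(traj, spec, config = config),
       truth = traj$truth, spec = spec)
}

#' Simulate a batch of paired trials and write them to disk
#'
#' Writes, per trial, an IMU file (`imu_<task>_<k>.csv`), a marker file
#' (`marker_<task>_<k>.csv`) and a ground-truth sidecar
#' (`truth_<task>_<k>.json`) into `out_dir`. Per-trial seeds are derived
#' deterministically from `seed`, so the same invocation reproduces the same
#' bytes.
#'
#' @param task Task label.
#' @param n_trials Number of trials (> 0).
#' @param seed Integer master seed.
#' @param out_dir Output directory (created if missing).
#' @param config Pipeline configuration.
#' @return Invisibly, a data frame listing trial ids and the three file paths.
#' @export
simulate_trials <- function(task, n_trials, seed, out_dir,
                            config = default_config()) {
  task <- match.arg(task, reachkin_tasks())
  if (!is.numeric(n_trials) || n_trials < 1)
    stop("n_trials must be a positive integer")
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  n_trials <- as.integer(n_trials)
  files <- vector("list", n_trials)
  for (k in seq_len(n_trials)) {
    sub_seed <- derive_seed(seed, task, k)
    id <- sprintf("%s-%03d", task, k)
    tr <- simulate_trial(task, sub_seed, config, trial_id = id)
    paths <- c(imu = file.path(out_dir, sprintf("imu_%s_%03d.csv", task, k)),
               marker = file.path(out_dir, sprintf("marker_%s_%03d.csv", task, k)),
               truth = file.path(out_dir, sprintf("truth_%s_%03d.json", task, k)))
    write_imu_trial(tr$imu, paths["imu"])
    write_marker_trial(tr$marker, paths["marker"])
    write_ground_truth(tr$truth, paths["truth"])
    files[[k]] <- data.frame(trial_id = id, task = task,
                             imu = unname(paths["imu"]),
                             marker = unname(paths["marker"]),
                             truth = unname(paths["truth"]))
  }
  invisible(do.call(rbind, files))
}

# Deterministic per-trial seed, kept well inside 32-bit integer range.
derive_seed <- function(seed, task, k) {
  base <- match(task, reachkin_tasks()) * 100000
  as.integer((abs(as.numeric(seed)) * 7919 + base + k) %% 2147483647)
}
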