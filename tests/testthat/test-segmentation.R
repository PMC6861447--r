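test_that("trimming keeps 100 frames around the significant movement", {
  n <- 600
  t <- (0:(n - 1)) / 100
  gz <- rep(0, n); gz[350:420] <- 30   # first exceedance at sample 350
  tr <- make_imu_trial(t, az = 1, gz = gz)
  b <- trim_trial(tr, velocity_preview = rep(0, n))
  expect_equal(b$trim_start, 250)
  expect_equal(b$trim_end, min(n, 420 + 100))
})

test_that("trim start clamps at the record boundary", {
  n <- 400
  t <- (0:(n - 1)) / 100
  gz <- rep(0, n); gz[50:80] <- 30
  tr <- make_imu_trial(t, az = 1, gz = gz)
  b <- trim_trial(tr, rep(0, n))
  expect_equal(b$trim_start, 1)
})

test_that("a static-only trial raises a no-movement error", {
  t <- (0:399) / 100
  tr <- make_imu_trial(t, az = 1)
  expect_error(trim_trial(tr, rep(0, 400)), class = "reachkin_no_movement")
})

test_that("the velocity predicate alone can trigger trimming", {
  n <- 500
  t <- (0:(n - 1)) / 100
  v <- rep(0, n); v[200:260] <- 0.5
  tr <- make_imu_trial(t, az = 1)
  b <- trim_trial(tr, v)
  expect_equal(b$trim_start, 100)
})

test_that("all-zero acceleration is fully stationary", {
  a_e <- matrix(0, 500, 3)
  mask <- stationary_mask(a_e, 100)
  expect_true(all(mask))
})

test_that("the envelope mask brackets a single movement burst", {
  spec <- trial_spec("block", list(
    segment_spec(c(0.3, 0, 0), 1, 1),
    segment_spec(c(0, 0.3, 0), 1, 1),
    segment_spec(c(-0.3, -0.3, 0), 1)),
    seed = 9, lead_in = 2, lead_out = 2)
  traj <- compose_trajectory(spec)
  t <- seq(0, traj$total_time, by = 0.01)
  a_e <- reachkin:::eval_trajectory(traj$segments, t)$acc
  mask <- stationary_mask(a_e, 100)
  # every burst is covered by the non-stationary label on >= 90% of its span
  for (k in 1:3) {
    burst <- t >= traj$segments$t_on[k] & t <= traj$segments$t_off[k]
    expect_gte(mean(!mask[burst]), 0.9)
  }
  # interior dwells of 1 s retain at least 0.5 s of stationary samples
  for (k in 1:2) {
    dwell <- t >= traj$segments$t_off[k] & t <= traj$segments$t_on[k + 1]
    expect_gte(sum(mask[dwell]) / 100, 0.5)
  }
})

test_that("trials shorter than the filter warm-up are rejected", {
  expect_error(stationary_mask(matrix(0, 50, 3), 100), "warm-up")
})

test_that("the gyro veto keeps rotating samples out of the stationary set", {
  a_e <- matrix(0, 500, 3)
  ang <- rep(0, 500); ang[200:300] <- 50
  mask <- stationary_mask(a_e, 100, angular_speed = ang)
  expect_true(all(!mask[200:300]))
  expect_true(all(mask[1:150]))
})

test_that("center section spans the qualifying angular-speed runs", {
  n <- 1200
  t <- (0:(n - 1)) / 100
  gz <- rep(0, n); gz[400:800] <- 30
  tr <- make_imu_trial(t, az = 1, gz = gz)
  sec <- split_sections(tr)
  expect_equal(sec$center_start, 400)
  expect_equal(sec$center_end, 800)

  gz2 <- rep(0, n); gz2[400:600] <- 30; gz2[700:900] <- 30
  sec2 <- split_sections(make_imu_trial(t, az = 1, gz = gz2))
  expect_equal(sec2$center_start, 400)
  expect_equal(sec2$center_end, 900)
})

test_that("a 9-frame gyro exceedance is not a movement", {
  n <- 600
  t <- (0:(n - 1)) / 100
  gz <- rep(0, n); gz[300:308] <- 30   # 9 frames only
  tr <- make_imu_trial(t, az = 1, gz = gz)
  expect_error(split_sections(tr), class = "reachkin_no_movement")
})

test_that("sectioning is idempotent on the trimmed trial", {
  tr <- simulate_trial("block", 43)$imu
  q <- ahrs_filter(tr); a_e <- to_earth_frame(tr, q)
  b <- trim_trial(tr, reachkin:::provisional_velocity(a_e), a_e)
  idx <- b$trim_start:b$trim_end
  sub <- reachkin:::new_imu_trial(as.data.frame(tr)[idx, ], 100, "block", "x")
  s1 <- split_sections(sub)
  s2 <- split_sections(sub)
  expect_identical(s1, s2)
})

test_that("the center section covers the bulk of every true movement segment", {
  for (seed in 44:46) {
    tr <- simulate_trial("drink", seed)
    res <- suppressWarnings(process_imu_trial(tr$imu))
    vp <- res$profile
    t_center <- vp$t[c(res$sections$center_start, res$sections$center_end)]
    truth <- tr$truth
    # the angular-speed rule clips the low-rotation fringes of the first and
    # last segments (the scripted wrist rotation crosses 10 deg/s a few
    # hundred ms inside each segment boundary); what matters for the metrics
    # is that every velocity-peak instant - each segment midpoint - lies
    # inside the center section
    mids <- (truth$seg_onsets + truth$seg_offsets) / 2
    expect_true(all(mids > t_center[1] & mids < t_center[2]))
    expect_lt(t_center[1], truth$seg_onsets[1] + 0.4)
    expect_gt(t_center[2], truth$seg_offsets[length(truth$seg_offsets)] - 0.4)
  }
})
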