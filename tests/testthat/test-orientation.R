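test_that("a static sensor with identity orientation is a fixed point", {
  t <- (0:499) / 100
  tr <- make_imu_trial(t, az = 1)
  q <- ahrs_filter(tr, beta = 0.1, q0 = c(1, 0, 0, 0))
  expect_lt(max(abs(q[, 1] - 1)), 1e-9)
  expect_lt(max(abs(q[, 2:4])), 1e-9)
})

test_that("pure gyro integration reproduces a 90-degree z rotation", {
  t <- (0:100) / 100
  tr <- make_imu_trial(t, az = 1, gz = 90)
  q <- ahrs_filter(tr, beta = 0, q0 = c(1, 0, 0, 0))
  q_true <- c(cos(pi / 4), 0, 0, sin(pi / 4))
  expect_lt(reachkin:::quat_angle(q[nrow(q), ], q_true), 1e-3)
})

test_that("the accelerometer correction recovers from a wrong initial orientation", {
  t <- (0:599) / 100
  tr <- make_imu_trial(t, az = 1)
  q0 <- reachkin:::quat_from_axis_angle(c(1, 0, 0), 20 * pi / 180)
  q <- ahrs_filter(tr, beta = 0.1, q0 = q0)
  # gravity direction error < 1 degree after 5 s
  g_est <- reachkin:::quat_rotate(q[501, ], c(0, 0, 1))
  ang <- acos(min(1, g_est[3])) * 180 / pi
  expect_lt(ang, 1)
})

test_that("zero-norm accelerometer samples skip the correction step", {
  t <- (0:199) / 100
  tr <- make_imu_trial(t, az = c(rep(1, 100), rep(0, 100)))
  expect_silent(q <- ahrs_filter(tr, beta = 0.1, q0 = c(1, 0, 0, 0)))
  expect_true(all(abs(sqrt(rowSums(q^2)) - 1) < 1e-9))
})

test_that("earth-frame transform cancels gravity for any static attitude", {
  t <- (0:299) / 100
  # sensor flipped 180 degrees about x: z points down, accelerometer reads -1 g
  tr <- make_imu_trial(t, az = -1)
  q <- ahrs_filter(tr, config = default_config())  # init from mean accel
  a_e <- to_earth_frame(tr, q)
  expect_lt(max(abs(a_e)), 1e-6)

  tr2 <- make_imu_trial(t, az = 1)
  a_e2 <- to_earth_frame(tr2, ahrs_filter(tr2))
  expect_lt(max(abs(a_e2)), 1e-6)
})

test_that("earth acceleration matches the analytic reach profile on noiseless input", {
  spec <- trial_spec("block", list(
    segment_spec(c(0.25, 0, 0), 1, 0.5),
    segment_spec(c(0.25, 0, 0), 1, 0.5),
    segment_spec(c(-0.5, 0, 0), 1)),
    seed = 8, accel_noise_sd = 0, gyro_noise_sd = 0, marker_noise_sd = 0,
    rotation_deg = 0)
  traj <- compose_trajectory(spec)
  imu <- imu_forward_model(traj, spec)
  q <- ahrs_filter(imu, beta = 0, q0 = c(1, 0, 0, 0))
  a_e <- to_earth_frame(imu, q)
  seg1 <- imu$t >= spec$lead_in & imu$t <= spec$lead_in + 1
  expected <- minimum_jerk_acceleration(0.25, 1, imu$t[seg1] - spec$lead_in)
  expect_lt(max(abs(a_e[seg1, 1] - expected)), 1e-6)
  expect_lt(max(abs(a_e[seg1, 3])), 1e-6)
})

test_that("orientation series and trial lengths must agree", {
  t <- (0:99) / 100
  tr <- make_imu_trial(t, az = 1)
  q <- ahrs_filter(tr)
  expect_error(to_earth_frame(make_imu_trial((0:49) / 100, az = 1), q),
               "different lengths")
})

test_that("quaternions stay unit norm and the filter is deterministic", {
  tr <- simulate_trial("pour", 41)$imu
  q1 <- ahrs_filter(tr)
  q2 <- ahrs_filter(tr)
  expect_identical(q1, q2)
  expect_lt(max(abs(sqrt(rowSums(q1^2)) - 1)), 1e-9)
})

test_that("integrated earth velocity stays small over stationary intervals", {
  # sensor noise only (a constant bias is the drift the ZUPT ramp removes)
  cfg <- default_config()
  cfg$simulate$accel_bias_sd <- 0
  tr <- simulate_trial("block", 42, cfg)$imu
  q <- ahrs_filter(tr, config = cfg)
  a_e <- to_earth_frame(tr, q)
  lead <- tr$t < 1.4
  v <- pracma::cumtrapz(tr$t[lead], a_e[lead, , drop = FALSE])
  expect_lt(max(sqrt(rowSums(v^2))), 0.08)
})
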