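test_that("noise-free tracks pass through the smoother almost unchanged", {
  t <- (0:999) / 200
  tr <- make_marker_trial(t, x = 100 + 50 * t, y = -20 * t, z = 3)
  expect_warning(sm <- smooth_markers(tr), "capped")
  expect_lt(max(abs(sm$x - tr$x)), 0.01)
  expect_lt(max(abs(sm$y - tr$y)), 0.01)
})

test_that("the smoothing penalty is solved to the requested residual MSE", {
  set.seed(7)
  t <- (0:1499) / 200
  tr <- make_marker_trial(t, x = 300 * sin(2 * pi * 0.5 * t) + rnorm(1500, 0, 2.5),
                          y = rnorm(1500, 0, 2.5), z = rnorm(1500, 0, 2.5))
  sm <- smooth_markers(tr, target_mse = 5)
  mse <- mean((sm$x - tr$x)^2)
  expect_gt(mse, 4.75); expect_lt(mse, 5.25)
})

test_that("smoothing is translation-equivariant", {
  set.seed(8)
  t <- (0:799) / 200
  x <- 100 * sin(2 * pi * t) + rnorm(800, 0, 1)
  tr1 <- make_marker_trial(t, x)
  tr2 <- make_marker_trial(t, x + 100)
  s1 <- suppressWarnings(smooth_markers(tr1, target_mse = 1))
  s2 <- suppressWarnings(smooth_markers(tr2, target_mse = 1))
  expect_equal(s2$x, s1$x + 100, tolerance = 1e-6)
})

test_that("central differences are exact for linear and quadratic tracks", {
  t <- (0:199) / 200
  # 10 mm per frame at 200 Hz = 2 m/s
  tr <- make_marker_trial(t, x = 10 * (0:199))
  vp <- differentiate(tr)
  expect_equal(vp$v[2:199], rep(2, 198), tolerance = 1e-12)
  expect_identical(vp$source, "reference")

  tr2 <- make_marker_trial(t, x = 1000 * t^2)
  v2 <- differentiate(tr2)
  # derivative of t^2 is 2t (in m/s: /1000 * 1000) - exactly linear
  expect_equal(v2$v[2:199], 2 * t[2:199], tolerance = 1e-10)
})

test_that("central-difference error on a 2 Hz sinusoid is below 0.1% of peak", {
  t <- (0:999) / 200
  A <- 100  # mm
  tr <- make_marker_trial(t, x = A * sin(2 * pi * 2 * t))
  vp <- differentiate(tr)
  analytic <- abs(A / 1000 * 2 * pi * 2 * cos(2 * pi * 2 * t))
  interior <- 2:999
  expect_lt(max(abs(vp$v[interior] - analytic[interior])),
            0.001 * max(analytic))
})

test_that("too-short marker tracks cannot be differentiated", {
  expect_error(differentiate(make_marker_trial(c(0, 0.005), x = c(0, 1))),
               "3 samples")
})

test_that("alignment crops by time across different sampling rates", {
  t <- (0:1999) / 200
  vp <- reachkin:::new_velocity_profile(rep(1, 2000), t, 200, "reference")
  out <- align_to_imu(vp, c(2.5, 6.5))
  expect_equal(length(out$v), 801)  # 4 s x 200 Hz + 1
  identical_win <- align_to_imu(vp, c(0, t[2000]))
  expect_equal(identical_win$v, vp$v)
  expect_warning(clamped <- align_to_imu(vp, c(5, 20)), "clamped")
  expect_equal(clamped$t[length(clamped$t)], t[2000])
  expect_error(align_to_imu(vp, c(30, 40)), "overlap")
})

test_that("the reference chain recovers noiseless ground truth", {
  cfg <- default_config()
  cfg$simulate$marker_noise_sd <- 0
  tr <- simulate_trial("block", 51, cfg)
  pr <- suppressWarnings(process_reference_trial(tr$marker, config = cfg))
  truth <- tr$truth
  expect_equal(pr$metrics$peak_velocity, truth$peak_velocity,
               tolerance = 0.005)
  # onset/offset land where the continuous speed profile crosses the
  # 2%-of-peak thresholds (independent root-finding oracle)
  seg <- compose_trajectory(tr$spec)$segments
  speed_at <- function(tt) sqrt(rowSums(reachkin:::eval_trajectory(seg, tt)$vel^2))
  pk <- attr(pr$metrics, "peak_indices")
  v <- pr$profile$v; tprof <- pr$profile$t
  thr_on <- 0.02 * v[pk[1]]
  thr_off <- 0.02 * v[pk[length(pk)]]
  t_on_true <- uniroot(function(x) speed_at(x) - thr_on,
                       c(seg$t_on[1], seg$t_on[1] + seg$duration[1] / 2))$root
  t_off_true <- uniroot(function(x) speed_at(x) - thr_off,
                        c(seg$t_off[3] - seg$duration[3] / 2, seg$t_off[3]))$root
  expect_lt(abs(tprof[pr$metrics$onset_idx] - t_on_true), 0.015)
  expect_lt(abs(tprof[pr$metrics$offset_idx] - t_off_true), 0.015)
})
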