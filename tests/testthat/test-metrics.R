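# A clean multi-hump profile builder: sum of minimum-jerk speed pulses.
pulse_profile <- function(peaks, starts, durs, rate = 100, total = NULL) {
  if (is.null(total)) total <- max(starts + durs) + 0.5
  t <- seq(0, total, by = 1 / rate)
  v <- numeric(length(t))
  for (k in seq_along(peaks)) {
    w <- t >= starts[k] & t <= starts[k] + durs[k]
    v[w] <- v[w] + peaks[k] / 1.875 * durs[k] *
      minimum_jerk_velocity(1, durs[k], t[w] - starts[k])
  }
  list(t = t, v = v)
}

test_that("escalating-threshold peak detection matches the exhaustive scan", {
  p <- pulse_profile(c(0.8, 1.1, 0.6), c(0.5, 2.0, 3.5), c(1, 1, 1))
  res <- detect_peaks(p$v, 3)
  expect_true(res$exact)
  expect_identical(res$n_found, 3L)
  oracle <- neighbor_scan_peaks(p$v, threshold = 0.1)
  expect_identical(length(oracle), 3L)
  expect_true(all(abs(res$peaks - oracle) <= 3))
})

test_that("sub-threshold noise bumps are not peaks", {
  p <- pulse_profile(c(0.08, 0.05, 0.7, 0.09, 0.9, 0.06, 0.07, 0.8),
                     c(0.3, 0.9, 1.5, 2.7, 3.2, 4.4, 4.8, 5.3),
                     rep(0.4, 8))
  res <- detect_peaks(p$v, 3)
  expect_true(res$exact)
  expect_identical(res$n_found, 3L)
  peak_vals <- p$v[res$peaks]
  expect_true(all(peak_vals > 0.5))
})

test_that("a flat profile raises a no-movement error", {
  expect_error(detect_peaks(rep(0, 500), 3), class = "reachkin_no_movement")
})

test_that("peak detection is invariant to stationary padding", {
  p <- pulse_profile(c(0.8, 1.1, 0.6), c(0.5, 2.0, 3.5), c(1, 1, 1))
  res1 <- detect_peaks(p$v, 3)
  padded <- c(rep(0, 200), p$v, rep(0, 200))
  res2 <- detect_peaks(padded, 3)
  expect_identical(res2$peaks - 200L, res1$peaks)
})

test_that("plateau peaks take the first sample", {
  v <- c(rep(0, 10), seq(0, 1, length.out = 20), rep(1, 5),
         seq(1, 0, length.out = 20), rep(0, 10))
  res <- detect_peaks(v, 1)
  expect_equal(res$peaks, 10 + 20)  # first sample of the plateau
})

test_that("the joint fallback uses the largest threshold where counts agree", {
  # both profiles show 2 humps; expected 3 never matches
  p <- pulse_profile(c(0.8, 0.9), c(0.5, 2), c(1, 1))
  q <- pulse_profile(c(0.7, 0.95), c(0.5, 2), c(1, 1))
  expect_warning(res <- detect_peaks(p$v, 3, other = q$v), "fallback")
  # at the largest threshold where both profiles agree, only the taller hump
  # survives
  expect_identical(res$n_found, 1L)
  expect_false(res$exact)
  # single-profile fallback: closest count with a warning
  expect_warning(res2 <- detect_peaks(p$v, 3), "closest")
  expect_identical(res2$n_found, 2L)
})

test_that("movement onset lands at the threshold crossing", {
  v <- c(rep(0, 199), rep(1, 500))
  onset <- find_onset(v, first_peak = 400, source = "reference")
  expect_equal(onset, 200)
  # quiet lead-in averaging above 0.05 defers the onset past the noisy span
  v2 <- c(rep(0.06, 150), rep(0.001, 50), seq(0, 1, length.out = 100),
          rep(1, 200))
  onset2 <- find_onset(v2, first_peak = which.max(v2), source = "reference")
  expect_gt(onset2, 150)
})

test_that("movement offset mirrors the onset with a trailing quiet window", {
  v <- c(rep(1, 899), rep(0, 300))
  offset <- find_offset(v, last_peak = 500, source = "reference")
  expect_equal(offset, 900)
  # trailing vibration defers the offset
  v2 <- c(rep(1, 300), seq(1, 0.001, length.out = 100), rep(0.07, 100),
          rep(0.001, 200))
  off2 <- find_offset(v2, last_peak = 150, source = "reference")
  expect_gt(off2, 380)
})

test_that("onset and offset track the simulator ground truth", {
  for (seed in 61:63) {
    tr <- simulate_trial("block", seed)
    res <- suppressWarnings(process_imu_trial(tr$imu))
    vp <- res$profile
    t_on <- vp$t[res$metrics$onset_idx]
    t_off <- vp$t[res$metrics$offset_idx]
    truth <- tr$truth
    expect_lt(abs(t_on - truth$seg_onsets[1]), 0.08)
    expect_lt(abs(t_off - truth$seg_offsets[length(truth$seg_offsets)]), 0.08)
  }
})

test_that("movement time is the onset-offset span in ms", {
  expect_equal(movement_time(200, 900, 100), 7000)
  expect_equal(movement_time(1, 1, 100), 0)
})

test_that("peak velocity is the maximum of the cropped profile", {
  t <- seq(0, 1, by = 0.01)
  v <- minimum_jerk_velocity(0.25, 1, t)
  expect_equal(peak_velocity(v, 1, length(v)), 0.46875)
  mono <- seq(0, 1, length.out = 50)
  expect_equal(peak_velocity(mono, 1, 50), mono[50])
  expect_error(peak_velocity(mono, 40, 30), "empty")
})

# independent SPARC oracle: trapezoid-rule arc length of the normalized
# spectrum over the band [0, fc], evaluated on a 10x denser zero-padded grid
sparc_oracle <- function(v, rate, fc) {
  nfft <- 2^ceiling(log2(160 * length(v)))
  V <- abs(fft(c(v, rep(0, nfft - length(v)))))[1:(nfft / 2 + 1)]
  f <- (0:(nfft / 2)) * rate / nfft
  keep <- f <= fc + 1e-9
  fk <- f[keep]; vn <- V[keep] / V[1]
  -sum(sqrt((diff(fk) / fc)^2 + diff(vn)^2))
}

test_that("spectral arc length equals the dense-grid oracle", {
  t <- seq(0, 1, by = 0.01)
  v <- minimum_jerk_velocity(0.25, 1, t)
  det <- sparc(v, 100, details = TRUE)
  expect_equal(det$sparc, sparc_oracle(v, 100, det$fc), tolerance = 1e-3)
  # the deep spectral nulls of a two-submovement profile are near-cusps of
  # the magnitude spectrum: the oracle on the same band still brackets the
  # value from below within the grid's corner-cutting error
  p <- pulse_profile(c(0.5, 0.5), c(0.2, 1.5), c(1, 1), total = 3)
  det2 <- sparc(p$v, 100, details = TRUE)
  oracle2 <- sparc_oracle(p$v, 100, det2$fc)
  expect_lte(oracle2, det2$sparc)
  expect_equal(det2$sparc, oracle2, tolerance = 0.05)
})

test_that("sparc is scale-invariant and penalizes submovements", {
  t <- seq(0, 1, by = 0.01)
  v <- minimum_jerk_velocity(0.25, 1, t)
  expect_equal(sparc(2 * v, 100), sparc(v, 100))
  single <- sparc(v, 100)
  p <- pulse_profile(c(0.469, 0.469), c(0.1, 1.4), c(1, 1), total = 2.6)
  expect_lt(sparc(p$v, 100), single)
  expect_lt(single, 0)
})

test_that("sparc is invariant to time shifts of the cropped profile", {
  t <- seq(0, 1, by = 0.01)
  v <- minimum_jerk_velocity(0.25, 1, t)
  shifted <- c(rep(0, 30), v)
  # magnitude spectrum is shift-invariant; padding changes nfft, so compare
  # at matched length
  expect_equal(sparc(c(v, rep(0, 30)), 100), sparc(shifted, 100),
               tolerance = 1e-9)
})

test_that("an all-zero profile has no defined smoothness", {
  expect_error(sparc(rep(0, 100), 100), class = "reachkin_undefined_metric")
})
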