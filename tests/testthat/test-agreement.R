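test_that("pearson_r matches the direct covariance formula", {
  expect_equal(pearson_r(1:5, 1:5), 1)
  expect_equal(pearson_r(1:5, -(1:5)), -1)
  a <- c(1, 2, 3, 4, 5); b <- c(2, 1, 4, 3, 6)
  direct <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(pearson_r(a, b), direct, tolerance = 1e-12)
  expect_error(pearson_r(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_r(1:2, 1:2), "at least 3")
})

test_that("icc_2_1 equals the independent two-way ANOVA decomposition", {
  A <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  B <- c(1.3, 1.9, 3.4, 3.8, 5.5, 6.1)
  res <- icc_2_1(A, B)
  # independent oracle: mean squares from aov()
  df <- data.frame(score = c(A, B),
                   subj = factor(rep(1:6, 2)),
                   rater = factor(rep(c("A", "B"), each = 6)))
  ms <- summary(aov(score ~ subj + rater, data = df))[[1]][["Mean Sq"]]
  MSR <- ms[1]; MSC <- ms[2]; MSE <- ms[3]
  n <- 6; k <- 2
  oracle <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))
  expect_equal(res$icc, oracle, tolerance = 1e-9)
})

test_that("icc_2_1 point estimate and F-based CI match an independent implementation", {
  # frozen from an independent ICC implementation (pingouin 0.6.1, ICC2)
  A <- c(9.0, 10.5, 12.0, 8.0, 11.2, 9.7, 10.1, 13.0)
  B <- c(9.4, 10.2, 12.8, 8.5, 10.9, 10.4, 10.0, 13.5)
  res <- icc_2_1(A, B)
  expect_equal(res$icc, 0.954723637789, tolerance = 1e-9)
  expect_equal(res$ci_low, 0.778635431723, tolerance = 1e-6)
  expect_equal(res$ci_high, 0.990894932411, tolerance = 1e-6)

  A2 <- c(1.0, 2.0, 3.0, 4.0, 5.0, 6.0)
  B2 <- c(1.3, 1.9, 3.4, 3.8, 5.5, 6.1)
  res2 <- icc_2_1(A2, B2)
  expect_equal(res2$icc, 0.986915887850, tolerance = 1e-9)
  expect_equal(res2$ci_low, 0.916461487638, tolerance = 1e-6)
  expect_equal(res2$ci_high, 0.998139869120, tolerance = 1e-6)
})

test_that("absolute agreement penalizes a constant offset, consistency does not", {
  A <- c(10, 20, 30, 40, 50, 60, 70, 80)
  B <- A + 5
  res <- icc_2_1(A, B)
  consistency <- (res$MSR - res$MSE) / (res$MSR + res$MSE)
  expect_lt(res$icc, 1)
  expect_lt(res$icc, consistency)
  expect_equal(icc_2_1(A, A + 0)$icc, 1)
})

test_that("icc_2_1 reduces to pearson_r without rater effects (constructed identity)", {
  set.seed(3)
  A <- rnorm(40, 10, 2)
  B <- 0.8 * A + rnorm(40, 0, 1)
  # equalize the marginal variance and engineer MSC == MSE exactly
  B <- (B - mean(B)) / sd(B) * sd(A) + mean(A)
  base <- icc_2_1(A, B)
  delta <- sqrt(2 * base$MSE / length(A))
  res <- icc_2_1(A, B + delta)
  expect_equal(res$MSC, res$MSE, tolerance = 1e-9)
  expect_equal(res$icc, pearson_r(A, B + delta), tolerance = 1e-6)
})

test_that("bland_altman recovers bias and limits of agreement", {
  A <- c(1, 2, 3, 4, 5)
  ident <- bland_altman(A, A)
  expect_equal(ident$bias, 0); expect_equal(ident$loa_low, 0)
  expect_equal(ident$cv_percent, 0)

  shifted <- bland_altman(A, A + 5)
  expect_equal(shifted$bias, 5)
  expect_equal(shifted$loa_low, 5); expect_equal(shifted$loa_high, 5)

  set.seed(11)
  a <- rnorm(10000, 100, 5)
  b <- a + rnorm(10000, 0, 10)
  ba <- bland_altman(a, b)
  half <- (ba$loa_high - ba$loa_low) / 2
  expect_gt(half, 19.2); expect_lt(half, 20.0)
  # LOA contain at least 93% of the differences
  inside <- mean(ba$diffs >= ba$loa_low & ba$diffs <= ba$loa_high)
  expect_gte(inside, 0.93)
})

test_that("agreement statistics are invariant to pair order", {
  set.seed(12)
  a <- rnorm(20); b <- a + rnorm(20, 0.1, 0.2)
  perm <- sample(20)
  expect_equal(pearson_r(a, b), pearson_r(a[perm], b[perm]))
  expect_equal(icc_2_1(a, b)$icc, icc_2_1(a[perm], b[perm])$icc)
  expect_equal(bland_altman(a, b)$bias, bland_altman(a[perm], b[perm])$bias)
})

test_that("the systematic-error check flags offsets and passes unbiased data", {
  set.seed(13)
  a <- rnorm(30, 10, 1)
  expect_true(systematic_error_check(a, a + rnorm(30, 0, 0.5))$no_systematic_error)
  res <- systematic_error_check(a, a + 3 + rnorm(30, 0, 0.01))
  expect_false(res$no_systematic_error)
  expect_equal(res$bias, 3, tolerance = 0.01)
})

test_that("validate_trials joins on trial ids and reports per-task metric rows", {
  m <- data.frame(trial_id = sprintf("b%02d", 1:10), task = "block",
                  movement_time_ms = seq(2800, 3600, length.out = 10),
                  peak_velocity = seq(0.9, 1.3, length.out = 10),
                  sparc = seq(-2.6, -2.1, length.out = 10))
  rep <- validate_trials(m, m)
  expect_equal(nrow(rep), 3)
  expect_true(all(rep$r == 1))
  expect_true(all(rep$bias == 0))
  expect_true(all(rep$no_systematic_error))
  # peak velocity is reported in mm/s
  expect_equal(rep$mean_imu[rep$metric == "peak_velocity"],
               mean(m$peak_velocity) * 1000)
  m2 <- m; m2$trial_id <- sprintf("x%02d", 1:10)
  expect_error(validate_trials(m, m2), "unmatched")
})
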