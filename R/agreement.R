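# Concurrent-validity statistics over paired per-trial metrics.

#' Pearson product-moment correlation between paired systems
#'
#' @param a,b Paired metric values (same trials, two systems); at least 3
#'   pairs with nonzero variance on both sides.
#' @return The correlation coefficient.
#' @export
pearson_r <- function(a, b) {
  check_pairs(a, b, 3)
  if (var(a) == 0 || var(b) == 0)
    stop("correlation undefined: a system has zero variance across trials")
  cor(a, b)
}

#' ICC(2,1): two-way random effects, absolute agreement, single measures
#'
#' Point estimate from the two-way ANOVA mean squares,
#' `(MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))` with `k = 2` raters
#' (systems) and `n` trials, and the 95% confidence interval from the
#' F-based procedure of McGraw & Wong. Absolute agreement penalizes a
#' constant offset between systems, unlike the consistency definition.
#'
#' @param a,b Paired metric values; at least 5 pairs.
#' @param conf_level Confidence level for the interval.
#' @return List with `icc`, `ci_low`, `ci_high` and the mean squares.
#' @export
icc_2_1 <- function(a, b, conf_level = 0.95) {
  check_pairs(a, b, 5)
  X <- cbind(a, b)
  n <- nrow(X); k <- ncol(X)
  gm <- mean(X)
  MSR <- k * sum((rowMeans(X) - gm)^2) / (n - 1)
  MSC <- n * sum((colMeans(X) - gm)^2) / (k - 1)
  SST <- sum((X - gm)^2)
  MSE <- (SST - MSR * (n - 1) - MSC * (k - 1)) / ((n - 1) * (k - 1))
  if (MSR <= 0) stop("degenerate ANOVA: no between-trial variance")
  icc <- (MSR - MSE) / (MSR + (k - 1) * MSE + k / n * (MSC - MSE))

  alpha <- 1 - conf_level
  av <- k * icc / (n * (1 - icc))
  bv <- 1 + k * icc * (n - 1) / (n * (1 - icc))
  v <- (av * MSC + bv * MSE)^2 /
    ((av * MSC)^2 / (k - 1) + (bv * MSE)^2 / ((n - 1) * (k - 1)))
  FL <- qf(1 - alpha / 2, n - 1, v)
  FU <- qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (MSR - FL * MSE) /
    (FL * (k * MSC + (k * n - k - n) * MSE) + n * MSR)
  ci_high <- n * (FU * MSR - MSE) /
    (k * MSC + (k * n - k - n) * MSE + n * FU * MSR)
  list(icc = icc, ci_low = ci_low, ci_high = ci_high,
       MSR = MSR, MSC = MSC, MSE = MSE, n = n, k = k)
}

#' Bland-Altman agreement statistics
#'
#' Differences are taken as `b - a` (device minus reference when called as
#' `bland_altman(reference, device)`). Returns the mean difference (bias),
#' the 95% limits of agreement `bias ± 1.96 SD(d)`, a coefficient of
#' variation (SD of differences over the grand mean of the paired averages,
#' in percent), and the (mean, difference) pairs for plotting.
#'
#' @param a,b Paired metric values (`a` = reference system, `b` = device).
#' @return List with `bias`, `loa_low`, `loa_high`, `cv_percent`, `means`,
#'   `diffs`, `n`.
#' @export
bland_altman <- function(a, b) {
  check_pairs(a, b, 2)
  d <- b - a
  m <- (a + b) / 2
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       cv_percent = 100 * s / mean(m), means = m, diffs = d, n = length(d))
}

#' Systematic-error check on the mean difference
#'
#' Declares "no systematic error" when zero lies inside the 95% confidence
#' interval of the mean between-device difference,
#' `bias ± t(0.975, n-1) SD(d)/sqrt(n)` (the line of equality falls within
#' the confidence band of the bias; the Student-t multiplier keeps the test
#' exactly at the 5% level for small trial counts, where the normal 1.96
#' would reject almost 6% of unbiased data at n = 30). Also reports the
#' regression slope of the differences on the pair means for
#' proportional-bias inspection.
#'
#' @param a,b Paired metric values; at least 5 pairs.
#' @return List with `no_systematic_error` (logical), `bias`, `ci_low`,
#'   `ci_high`, `slope`.
#' @export
systematic_error_check <- function(a, b) {
  check_pairs(a, b, 5)
  d <- b - a
  m <- (a + b) / 2
  n <- length(d)
  bias <- mean(d)
  se <- sd(d) / sqrt(n)
  ci <- bias + c(-1, 1) * stats::qt(0.975, n - 1) * se
  slope <- if (var(m) > 0) unname(coef(lm(d ~ m))[2]) else 0
  list(no_systematic_error = ci[1] <= 0 && 0 <= ci[2],
       bias = bias, ci_low = ci[1], ci_high = ci[2], slope = slope)
}

check_pairs <- function(a, b, n_min) {
  if (length(a) != length(b)) stop("paired vectors of different length")
  if (anyNA(a) || anyNA(b)) stop("missing values in paired metrics")
  if (length(a) < n_min)
    stop(sprintf("need at least %d pairs, got %d", n_min, length(a)))
  invisible(TRUE)
}

#' Build the per-task, per-metric agreement report
#'
#' Joins the two metric tables on `trial_id` within each task and computes,
#' for movement time (ms), spectral arc length, and peak velocity (reported
#' in mm/s following the clinical convention), the two systems' means,
#' Pearson r, ICC(2,1) with 95% CI, Bland-Altman bias and limits of
#' agreement, the difference CV%, and the systematic-error verdict.
#' Differences are device minus reference (IMU - optical).
#'
#' @param metrics_imu,metrics_ref `trial_metrics` tables with `trial_id` and
#'   `task` columns (as produced by [process_trials()]).
#' @param config Pipeline configuration.
#' @return An `agreement_report` data frame.
#' @export
validate_trials <- function(metrics_imu, metrics_ref, config = default_config()) {
  need <- c("trial_id", "task", "movement_time_ms", "peak_velocity", "sparc")
  for (nm in need) {
    if (!nm %in% names(metrics_imu) || !nm %in% names(metrics_ref))
      stop("metrics tables must contain column: ", nm)
  }
  unmatched <- c(setdiff(metrics_imu$trial_id, metrics_ref$trial_id),
                 setdiff(metrics_ref$trial_id, metrics_imu$trial_id))
  if (length(unmatched))
    stop("unmatched trial ids between systems: ",
         paste(utils::head(unique(unmatched), 10), collapse = ", "))
  merged <- merge(metrics_imu[need], metrics_ref[need],
                  by = c("trial_id", "task"), suffixes = c("_imu", "_ref"))
  if (nrow(merged) == 0) stop("no paired trials to validate")

  metric_defs <- data.frame(
    metric = c("movement_time", "sparc", "peak_velocity"),
    col = c("movement_time_ms", "sparc", "peak_velocity"),
    units = c("ms", "dimensionless", "mm/s"),
    scale = c(1, 1, 1000))  # peak velocity reported in mm/s

  rows <- list()
  for (task in sort(unique(merged$task))) {
    sub <- merged[merged$task == task, ]
    for (j in seq_len(nrow(metric_defs))) {
      col <- metric_defs$col[j]; sc <- metric_defs$scale[j]
      ref <- sub[[paste0(col, "_ref")]] * sc
      imu <- sub[[paste0(col, "_imu")]] * sc
      icc <- icc_2_1(ref, imu)
      ba <- bland_altman(ref, imu)
      sec <- systematic_error_check(ref, imu)
      rows[[length(rows) + 1]] <- data.frame(
        task = task, metric = metric_defs$metric[j],
        units = metric_defs$units[j], n = length(ref),
        mean_ref = mean(ref), mean_imu = mean(imu),
        r = pearson_r(ref, imu),
        icc = icc$icc, icc_ci_low = icc$ci_low, icc_ci_high = icc$ci_high,
        bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
        cv_percent = ba$cv_percent,
        no_systematic_error = sec$no_systematic_error)
    }
  }
  structure(do.call(rbind, rows), class = c("agreement_report", "data.frame"))
}

#' @export
print.agreement_report <- function(x, digits = 3, ...) {
  cat("Concurrent validity: IMU vs reference (differences are IMU - reference)\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) signif(v, digits))
  print.data.frame(df, row.names = FALSE)
  invisible(x)
}
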