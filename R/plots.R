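#' Bland-Altman plot for one metric
#'
#' Scatter of between-device differences against pair means with the bias
#' and 95% limits of agreement drawn as horizontal lines.
#'
#' @param a,b Paired metric values (`a` = reference, `b` = device).
#' @param xlab,ylab,main Plot labels.
#' @param ... Passed to [graphics::plot()].
#' @return The [bland_altman()] result, invisibly.
#' @export
plot_bland_altman <- function(a, b, xlab = "mean of systems",
                              ylab = "difference (IMU - reference)",
                              main = "Bland-Altman", ...) {
  ba <- bland_altman(a, b)
  graphics::plot(ba$means, ba$diffs, xlab = xlab, ylab = ylab, main = main, ...)
  abline(h = ba$bias, lty = 1)
  abline(h = c(ba$loa_low, ba$loa_high), lty = 2)
  invisible(ba)
}
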