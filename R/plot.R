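# Base-graphics views of decoding results: mean curves with significance
# discs above the time axis and peak markers, one color per condition.

#' Plot group-level decoding curves
#'
#' Overlays the mean decoding curves of one or more group results, marks
#' timepoints whose one-sided test is significant with discs above the
#' time axis, and marks each curve's maximum.
#'
#' @param results a [GroupResult-class] or named list of them (one per
#'   grid level).
#' @param chance horizontal reference level.
#' @param main plot title.
#' @param ylim y-axis limits; derived from the data when NULL.
#' @return invisibly, NULL.
#' @export
plotGroupResults <- function(results, chance = 0.5, main = "Decoding",
                             ylim = NULL) {
  if (is(results, "GroupResult")) results <- list(result = results)
  cols <- grDevices::hcl.colors(max(3L, length(results)), "Dark 3")
  times <- results[[1L]]@times
  accs <- lapply(results, slot, "meanAccuracy")
  if (is.null(ylim)) {
    rng <- range(unlist(accs), chance)
    ylim <- rng + c(-0.12, 0.05) * diff(rng + c(0, 1e-9))
  }
  graphics::plot(NULL, xlim = range(times), ylim = ylim,
                 xlab = "time (s)", ylab = "accuracy", main = main)
  graphics::abline(h = chance, lty = 3, col = "grey40")
  graphics::abline(v = 0, lty = 3, col = "grey40")
  discY <- ylim[1L] + 0.02 * diff(ylim) * seq_along(results)
  for (i in seq_along(results)) {
    r <- results[[i]]
    graphics::lines(r@times, r@meanAccuracy, col = cols[i], lwd = 1.5)
    if (any(r@significant))
      graphics::points(r@times[r@significant],
                       rep(discY[i], sum(r@significant)),
                       pch = 16, cex = 0.4, col = cols[i])
    imax <- which.max(r@meanAccuracy)
    graphics::points(r@times[imax], r@meanAccuracy[imax], pch = 17,
                     col = cols[i])
  }
  if (length(results) > 1L)
    graphics::legend("topright", legend = names(results), col = cols,
                     lwd = 1.5, bty = "n", cex = 0.8)
  invisible(NULL)
}
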