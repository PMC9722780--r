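# Base-graphics views of classification images and impact curves.

#' Plot impact curves
#'
#' Center (red) and surround (blue) weight traces against time before the
#' response, with the response at the right edge (time axis reversed).
#'
#' @param curves an `impact_curves` data frame.
#' @param main plot title.
#' @param ... passed to [graphics::matplot()].
#' @export
plot_impact_curves <- function(curves, main = "Impact curves", ...) {
  graphics::matplot(-curves$lag_ms, cbind(curves$center, curves$surround),
                    type = "l", lty = 1, lwd = 2, col = c("firebrick", "steelblue"),
                    xlab = "Time from response (ms)",
                    ylab = "Weight (contrast units)", main = main, ...)
  graphics::abline(h = 0, col = "grey60", lty = 2)
  graphics::legend("topleft", c("center (bars 8-9)", "surround (bars 7,10)"),
                   col = c("firebrick", "steelblue"), lwd = 2, bty = "n")
}

#' Plot a classification image
#'
#' Space (bars) against time before the response, weights as gray levels;
#' the layout of the usual CI panels (response at the right edge).
#'
#' @param ci an `rlci_ci` object.
#' @param main plot title.
#' @export
plot_ci <- function(ci, main = "Response-locked classification image") {
  w <- ci$weights
  graphics::image(-rev(ci$lag_ms), seq_len(nrow(w)),
                  t(w[, ncol(w):1, drop = FALSE]),
                  col = grDevices::grey.colors(64, 0, 1),
                  xlab = "Time from response (ms)", ylab = "Bar", main = main)
}
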