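# ---- QC and summary plots (base graphics) -----------------------------------

#' QC plot of a cell-wall gray profile with detected landmarks
#'
#' Profile points, the fitted ring spline and vertical markers at the
#' cambium (green), the maturing/mature transition (blue) and the previous
#' ring boundary (yellow).
#'
#' @param profile a cell-wall \code{\link{gray_profile}}.
#' @param widths a \code{\link{measure_widths}} result.
#' @return invisibly, NULL.
#' @export
plot_ring_profile <- function(profile, widths) {
  graphics::plot(profile$position, profile$value, pch = 16, cex = 0.4,
                 col = "gray40", xlab = "radial position (um, bark to pith)",
                 ylab = "mean cell-wall gray value",
                 main = "Cell-wall gray profile")
  seg <- profile_window(profile, widths$cambium_pos, widths$prev_boundary_pos)
  if (nrow(seg) >= 2 && !is.null(widths$fit))
    graphics::lines(seg$position,
                    predict(widths$fit, seg$position - widths$cambium_pos),
                    col = "red", lwd = 2)
  graphics::abline(v = widths$cambium_pos, col = "forestgreen", lwd = 2)
  graphics::abline(v = widths$transition_pos, col = "royalblue", lwd = 2)
  graphics::abline(v = widths$prev_boundary_pos, col = "goldenrod", lwd = 2)
  graphics::legend("topleft", bty = "n", lwd = 2,
                   col = c("forestgreen", "royalblue", "goldenrod"),
                   legend = c("cambium", "transition", "previous boundary"))
  invisible(NULL)
}

#' Completion and rate curves with the time-lag trace
#'
#' Top panel: width and biomass completion curves; bottom panel: their daily
#' rates with peak markers.
#'
#' @param completion result of \code{\link{completion_curves}}.
#' @param peaks result of \code{\link{peak_rate_lag}} (optional).
#' @return invisibly, NULL.
#' @export
plot_completion_lag <- function(completion, peaks = NULL) {
  op <- graphics::par(mfrow = c(2, 1), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  w <- completion$width; b <- completion$biomass
  graphics::plot(w$doy, w$completion, type = "l", lwd = 2, col = "forestgreen",
                 xlab = "day of year", ylab = "relative completion",
                 ylim = range(c(w$completion, b$completion)))
  graphics::lines(b$doy, b$completion, lwd = 2, col = "sienna")
  graphics::abline(h = c(0.05, 0.95), lty = 3)
  graphics::legend("bottomright", bty = "n", lwd = 2,
                   col = c("forestgreen", "sienna"),
                   legend = c("size (w_incr)", "biomass (b_trunk)"))
  rw <- data.frame(doy = w$doy[-1], rate = diff(w$completion))
  rb <- data.frame(doy = b$doy[-1], rate = diff(b$completion))
  graphics::plot(rw$doy, rw$rate, type = "l", lwd = 2, col = "forestgreen",
                 xlab = "day of year", ylab = "daily rate (fraction/day)",
                 ylim = range(c(rw$rate, rb$rate)))
  graphics::lines(rb$doy, rb$rate, lwd = 2, col = "sienna")
  if (!is.null(peaks) && !peaks$undefined) {
    graphics::abline(v = peaks$doy_width_peak, col = "forestgreen", lty = 2)
    graphics::abline(v = peaks$doy_biomass_peak, col = "sienna", lty = 2)
  }
  invisible(NULL)
}
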