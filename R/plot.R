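## Base-graphics displays of diel activity, in the style customary for
## camera-trap activity analyses.

#' Plot a diel activity density
#'
#' Kernel density as a solid line over the 24-h axis, optionally with a
#' trigonometric-sum fit dashed on top, a rug of event times, and dotted
#' guides at the twilight window boundaries.
#'
#' @param x an `activity_density` from [vm_kernel_density()].
#' @param trig optional second `activity_density` (dashed).
#' @param times optional event times (radians) for the rug.
#' @param solar [solar_schedule()] for the twilight guides; `NULL` for
#'   none.
#' @param main title.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, `NULL`.
#' @export
plot_activity <- function(x, trig = NULL, times = NULL,
                          solar = solar_schedule(), main = "", ...) {
  h <- radians_to_hours(x$grid)
  ord <- order(h)
  ## densities per hour so the y-axis reads events h^-1
  y <- x$density[ord] * pi / 12
  graphics::plot(h[ord], y, type = "l", xlim = c(0, 24),
                 ylim = c(0, max(y) * 1.15), xaxs = "i",
                 xlab = "Time of day (h)", ylab = "Density (h⁻¹)",
                 main = main, xaxt = "n", ...)
  graphics::axis(1, at = seq(0, 24, 6))
  if (!is.null(trig)) {
    graphics::lines(radians_to_hours(trig$grid)[ord],
                    trig$density[ord] * pi / 12, lty = 2)
  }
  if (!is.null(solar)) {
    tw <- solar$twilight_halfwidth
    graphics::abline(v = c(solar$sunrise - tw, solar$sunrise,
                           solar$sunrise + tw, solar$sunset - tw,
                           solar$sunset, solar$sunset + tw),
                     lty = 3, col = "grey50")
  }
  if (!is.null(times)) graphics::rug(radians_to_hours(times))
  invisible(NULL)
}

#' Rose diagram of diel event times
#'
#' Relative frequencies in hourly sectors drawn on the clock circle, with
#' an arrow at the circular median.
#'
#' @param times event times in radians.
#' @param n_bins sectors (default 24).
#' @param main title.
#' @return invisibly, the bin frequencies.
#' @export
plot_rose <- function(times, n_bins = 24L, main = "") {
  freq <- rose_bins(times, n_bins)
  r <- sqrt(freq / max(freq))          # area-true sector radii
  graphics::plot(NA, xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3), asp = 1,
                 axes = FALSE, xlab = "", ylab = "", main = main)
  ## clock orientation: midnight up, hours clockwise
  ang0 <- pi / 2 - (seq_len(n_bins) - 1) * 2 * pi / n_bins
  for (k in seq_len(n_bins)) {
    aa <- seq(ang0[k], ang0[k] - 2 * pi / n_bins, length.out = 10)
    graphics::polygon(c(0, r[k] * cos(aa)), c(0, r[k] * sin(aa)),
                      col = "grey80")
  }
  graphics::symbols(0, 0, circles = 1, inches = FALSE, add = TRUE)
  for (hh in c(0, 6, 12, 18)) {
    a <- pi / 2 - hours_to_radians(hh)
    graphics::text(1.18 * cos(a), 1.18 * sin(a), sprintf("%02d:00", hh))
  }
  med <- pi / 2 - circular_median(times)
  graphics::arrows(0, 0, 0.8 * cos(med), 0.8 * sin(med), length = 0.08)
  invisible(freq)
}
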