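# Base-graphics views of the main objects.

#' Raster plot of a spike record
#' @param x a `spike_record`.
#' @param population population to draw (default: oscillating population).
#' @param t_lim time range (ms).
#' @param ... passed to [plot()].
#' @export
plot.spike_record <- function(x, population = NULL, t_lim = NULL, ...) {
  population <- population %||% attr(x, "osc_population")
  d <- x[x$population == population, ]
  if (!is.null(t_lim)) d <- d[d$t >= t_lim[1] & d$t <= t_lim[2], ]
  plot(d$t, d$neuron, pch = ".", xlab = "time (ms)", ylab = "neuron",
       main = sprintf("%s raster", population), ...)
  invisible(x)
}

#' Plot a power spectrum
#' @param x a `spectral_summary`.
#' @param f_lim frequency range (Hz).
#' @param ... passed to [plot()].
#' @export
plot.spectral_summary <- function(x, f_lim = c(0, 100), ...) {
  sel <- x$freq >= f_lim[1] & x$freq <= f_lim[2]
  plot(x$freq[sel], x$power[sel], type = "l", xlab = "frequency (Hz)",
       ylab = "power", ...)
  graphics::abline(v = x$beta_band, lty = 3, col = "red")
  graphics::abline(v = x$gamma_band, lty = 3, col = "grey")
  invisible(x)
}

#' Plot a PRC estimate with its smoothed fit
#' @param x a `prc_estimate`.
#' @param harmonics smoothing harmonics for the overlay.
#' @param ... passed to [plot()].
#' @export
plot.prc_estimate <- function(x, harmonics = 4, ...) {
  plot(x$bin_center, x$mean_advance, pch = 16, xlab = "stimulus phase (cycles)",
       ylab = "phase advance (cycles)", ylim = range(c(
         x$mean_advance - x$circ_std, x$mean_advance + x$circ_std), na.rm = TRUE),
       ...)
  graphics::arrows(x$bin_center, x$mean_advance - x$circ_std, x$bin_center,
                   x$mean_advance + x$circ_std, angle = 90, code = 3,
                   length = 0.02, col = "grey50")
  Zf <- prc_function(x, harmonics = harmonics)
  g <- seq(0, 1, length.out = 200)
  graphics::lines(g, prc_value(Zf, g), col = "red")
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Plot a divergence prediction curve
#' @param x a `divergence_curve`.
#' @param ... passed to [plot()].
#' @export
plot.divergence_curve <- function(x, ...) {
  plot(x$phi, x$minus_slope, type = "l", xlab = "stimulus phase (cycles)",
       ylab = expression(-Z * minute * (phi)), ...)
  graphics::abline(h = 0, lty = 3, col = "red")
  invisible(x)
}
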