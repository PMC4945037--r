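# Turning a PRC into predictions: the PRC map, the pair-separation (slope)
# criterion, the multi-pulse divergence factor, and the optimal stimulus
# (phase, inter-pulse interval) search.
#
# A binned, noisy PRC cannot be differentiated directly; it is first
# projected onto a small trigonometric basis (periodic least squares,
# default 4 harmonics), which is smooth, strictly periodic and has an
# analytic derivative that integrates to zero over one period.

#' Smooth periodic representation of a PRC
#'
#' @param x a `prc_estimate`, a function of phase (cycles), or a numeric
#'   vector sampling Z on a uniform grid over `[0, 1)`.
#' @param harmonics number of harmonics retained.
#' @param weights per-bin weights for a `prc_estimate` (default: bin counts).
#' @return A `prc_function` with fields `a0`, `a`, `b` such that
#'   `Z(phi) = a0 + sum_h a_h cos(2 pi h phi) + b_h sin(2 pi h phi)`.
#' @export
prc_function <- function(x, harmonics = 4, weights = NULL) {
  if (inherits(x, "prc_function")) return(x)
  if (inherits(x, "prc_estimate")) {
    ok <- !is.na(x$mean_advance)
    if (sum(ok) < 4) stop("too few non-empty bins to smooth a PRC")
    if (sum(ok) < 2 * harmonics + 1)
      harmonics <- max(1L, floor((sum(ok) - 1) / 2))
    phi <- x$bin_center[ok]; z <- x$mean_advance[ok]
    w <- (weights %||% x$count)[ok]
  } else {
    if (is.function(x)) {
      phi <- (0:255) / 256; z <- x(phi)
    } else {
      z <- as.numeric(x); phi <- (seq_along(z) - 1) / length(z)
    }
    w <- rep(1, length(phi))
  }
  H <- harmonics
  M <- cbind(1, do.call(cbind, lapply(seq_len(H), function(h)
    cbind(cos(2 * pi * h * phi), sin(2 * pi * h * phi)))))
  fit <- stats::lm.wfit(M, z, w)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  a <- cf[2 * seq_len(H)]; b <- cf[2 * seq_len(H) + 1]
  structure(list(a0 = cf[[1]], a = unname(a), b = unname(b), harmonics = H),
            class = "prc_function")
}

#' Evaluate a smoothed PRC
#' @param Z a [prc_function()].
#' @param phi phase(s) in cycles.
#' @return `Z(phi)` in cycles per stimulus.
#' @export
prc_value <- function(Z, phi) {
  h <- seq_len(Z$harmonics)
  out <- rep(Z$a0, length(phi))
  for (k in h)
    out <- out + Z$a[k] * cos(2 * pi * k * phi) + Z$b[k] * sin(2 * pi * k * phi)
  out
}

#' Derivative of a smoothed PRC
#' @inheritParams prc_value
#' @return `Z'(phi)` (dimensionless, cycles per cycle); periodic and
#'   integrating to zero over one period.
#' @export
prc_slope <- function(Z, phi) {
  out <- rep(0, length(phi))
  for (k in seq_len(Z$harmonics))
    out <- out + 2 * pi * k * (-Z$a[k] * sin(2 * pi * k * phi) +
                                 Z$b[k] * cos(2 * pi * k * phi))
  out
}

#' The PRC map
#'
#' Next-cycle stimulus phase under once-per-cycle stimulation:
#' `phi_{i+1} = (phi_i + Z(phi_i)) mod 1`.
#'
#' @param Z a [prc_function()] (or anything [prc_function()] accepts).
#' @param phi current phase(s), cycles.
#' @export
prc_map <- function(Z, phi) {
  Z <- prc_function(Z)
  wrap_phase(phi + prc_value(Z, phi))
}

#' Next-cycle separation of two nearby oscillators after one pulse
#'
#' `eps_{i+1} = eps_i * (1 + Z'(phi_i))`: phases where the PRC slope is
#' positive are desynchronizing.
#'
#' @param Z a [prc_function()].
#' @param phi stimulus phase (cycles).
#' @param eps current separation (cycles); keep `|eps| < 0.05` for the
#'   linearization to be meaningful.
#' @export
pair_separation_single <- function(Z, phi, eps) {
  Z <- prc_function(Z)
  eps * (1 + prc_slope(Z, phi))
}

#' Separation growth across a burst of pulses
#'
#' Implements the multi-pulse divergence factor for a burst of `n` pulses
#' separated by `delta` cycles: each pulse contributes a factor
#' `1 + Z_k'(arg_k)` where `arg_k = phi + sum_{j<k} Z_j(arg_j) + (k-1) delta`
#' accumulates the resetting of earlier pulses plus the inter-pulse drift.
#' For three pulses this is the literal three-factor product; the same
#' recursion generalizes to any number of pulses.
#'
#' @param Z1,Z2,Z3 per-pulse PRCs ([prc_function()]s); `Z2`, `Z3` default to
#'   `Z1` (identical first-order resetting).
#' @param phi phase of the first pulse (cycles); vectorized.
#' @param delta inter-stimulus interval in cycles.
#' @param eps initial separation (cycles).
#' @param Zs optional list of PRCs, one per pulse, overriding `Z1..Z3`
#'   (any number of pulses).
#' @return `eps` times the product of per-pulse factors.
#' @export
divergence_burst <- function(Z1, Z2 = Z1, Z3 = Z1, phi, delta, eps = 1,
                             Zs = NULL) {
  Zs <- Zs %||% list(Z1, Z2, Z3)
  Zs <- lapply(Zs, prc_function)
  growth <- rep(1, length(phi))
  cum <- rep(0, length(phi))
  for (k in seq_along(Zs)) {
    arg <- phi + cum + (k - 1) * delta
    growth <- growth * (1 + prc_slope(Zs[[k]], arg))
    cum <- cum + prc_value(Zs[[k]], arg)
  }
  eps * growth
}

#' First-order composed burst PRC
#'
#' The total phase advance of a burst predicted from a single-pulse PRC by
#' linear summation (no interactions between pulses):
#' `Z_burst(phi) = sum_k Z(arg_k)` with the same argument recursion as
#' [divergence_burst()].  A directly measured burst PRC that differs from
#' this composition indicates higher-order resetting.
#'
#' @param Z single-pulse [prc_function()].
#' @param pulses pulses per burst.
#' @param delta inter-stimulus interval in cycles.
#' @return A [prc_function()] of the composed burst PRC.
#' @export
compose_burst_prc <- function(Z, pulses = 3, delta) {
  Z <- prc_function(Z)
  grid <- (0:255) / 256
  cum <- rep(0, length(grid))
  for (k in seq_len(pulses)) {
    arg <- grid + cum + (k - 1) * delta
    cum <- cum + prc_value(Z, arg)
  }
  prc_function(cum, harmonics = Z$harmonics)
}

#' Divergence prediction curve over all phases
#'
#' Smooths a measured PRC, then computes the per-phase separation growth
#' factor for a burst (or single pulse) together with the `-Z'(phi)`
#' prediction curve.  Phases with growth above 1 (equivalently `-Z' < 0`
#' for one small pulse) are predicted to desynchronize, i.e. suppress the
#' population oscillation.
#'
#' @param Z a `prc_estimate` or [prc_function()] (needs at least 4
#'   non-empty bins).
#' @param pulses pulses per burst.
#' @param delta_ms inter-stimulus interval (ms).
#' @param period_ms oscillation period (ms) used to convert `delta_ms` to
#'   cycles.
#' @param n_grid phase grid resolution.
#' @param harmonics smoothing harmonics.
#' @return A `divergence_curve` data.frame: `phi`, `growth` (absolute
#'   multiplicative separation growth per cycle), `minus_slope`.
#'   Attribute `negative_factor` flags phases where a factor `1 + Z' < 0`
#'   (overcorrection); values are flagged, not clipped.
#' @export
prediction_curve <- function(Z, pulses = 3, delta_ms = 5,
                             period_ms = NOMINAL_PERIOD_MS, n_grid = 256,
                             harmonics = 4) {
  Zf <- prc_function(Z, harmonics = harmonics)
  delta <- delta_ms / period_ms
  phi <- (seq_len(n_grid) - 1) / n_grid
  raw <- divergence_burst(phi = phi, delta = delta, eps = 1,
                          Zs = rep(list(Zf), pulses))
  out <- data.frame(phi = phi, growth = abs(raw),
                    minus_slope = -prc_slope(Zf, phi))
  class(out) <- c("divergence_curve", "data.frame")
  attr(out, "pulses") <- pulses
  attr(out, "delta_cycles") <- delta
  attr(out, "negative_factor") <- raw < 0
  out
}

#' Optimal stimulus phase and inter-pulse interval
#'
#' Grid search over (phase, delta) maximizing the burst divergence growth;
#' ties are broken toward the smallest delta.  With one pulse the interval
#' is irrelevant and the optimum is the phase of steepest positive PRC
#' slope.
#'
#' @param Z a `prc_estimate` or [prc_function()].
#' @param pulses pulses per burst.
#' @param period_ms oscillation period (ms).
#' @param delta_bounds_ms range of intervals searched (ms).
#' @param n_phase,n_delta grid resolution.
#' @param harmonics smoothing harmonics.
#' @return List with `phase`, `delta_ms`, `growth`.
#' @export
optimize_stimulus <- function(Z, pulses = 3, period_ms = NOMINAL_PERIOD_MS,
                              delta_bounds_ms = c(1, 10), n_phase = 256,
                              n_delta = 46, harmonics = 4) {
  if (length(delta_bounds_ms) != 2 || diff(delta_bounds_ms) < 0)
    stop("empty delta bounds")
  Zf <- prc_function(Z, harmonics = harmonics)
  phi <- (seq_len(n_phase) - 1) / n_phase
  if (pulses == 1) {
    g <- 1 + prc_slope(Zf, phi)
    i <- which.max(g)   # phase of steepest positive slope
    return(list(phase = phi[i], delta_ms = NA_real_, growth = abs(g[i])))
  }
  deltas <- seq(delta_bounds_ms[1], delta_bounds_ms[2], length.out = n_delta)
  best <- list(phase = NA_real_, delta_ms = NA_real_, growth = -Inf)
  for (d in deltas) {   # increasing: first hit wins ties toward small delta
    raw <- divergence_burst(phi = phi, delta = d / period_ms, eps = 1,
                            Zs = rep(list(Zf), pulses))
    g <- abs(raw)
    i <- which.max(g)
    if (g[i] > best$growth + 1e-12)
      best <- list(phase = phi[i], delta_ms = d, growth = g[i])
  }
  best
}

#' Fraction of the phase axis with positive PRC slope
#'
#' @param Z a `prc_estimate` or [prc_function()].
#' @param n_grid evaluation grid size.
#' @param harmonics smoothing harmonics.
#' @return Fraction of `[0, 1)` where the smoothed `Z'` is positive.
#' @export
positive_slope_fraction <- function(Z, n_grid = 512, harmonics = 4) {
  Zf <- prc_function(Z, harmonics = harmonics)
  phi <- (seq_len(n_grid) - 1) / n_grid
  mean(prc_slope(Zf, phi) > 0)
}

#' Write a divergence curve as columnar text
#' @param curve a `divergence_curve`.
#' @param path output file.
#' @export
write_divergence_curve <- function(curve, path) {
  write.table(data.frame(phi = curve$phi, growth = curve$growth,
                         minus_slope = curve$minus_slope),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
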