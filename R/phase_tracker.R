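# Online phase estimation from spike times.  The estimator fits a
# time-weighted Fourier coefficient to the oscillation population's spikes
# in the trailing window and reads the instantaneous phase from the summed
# beta-band coefficients.  Phases are in cycles [0, 1).

#' Phase-tracker configuration
#'
#' @param window_T trailing window length (ms).
#' @param tau time constant of the exponential time weighting (ms).  Note
#'   `tau << window_T`: the weights decay e-fold every `tau` ms, so the
#'   effective memory is much shorter than the window.
#' @param f_min,f_max,f_step frequency grid (Hz) summed for the phase.
#' @param eval_dt evaluation cadence (ms) of the online estimator.
#' @return A `phase_tracker_config` object.
#' @export
phase_tracker_config <- function(window_T = 400, tau = 3, f_min = 30,
                                 f_max = 36, f_step = 1, eval_dt = 0.5) {
  stopifnot(f_min > 0, f_min <= f_max, window_T > 0, tau > 0, eval_dt > 0)
  structure(list(window_T = window_T, tau = tau, f_min = f_min,
                 f_max = f_max, f_step = f_step, eval_dt = eval_dt),
            class = "phase_tracker_config")
}

tracker_freqs <- function(config) seq(config$f_min, config$f_max, by = config$f_step)

#' Time-weighted Fourier coefficient of a spike train
#'
#' Computes `X(f, t) = sum_k exp((S_k - t)/tau) * exp(-2 pi i f S_k)` over
#' spikes `S_k` in `[t - window_T, t]`.  Spikes outside the window contribute
#' nothing.  With no spikes in the window the coefficient is 0 and the
#' result is flagged low-confidence.
#'
#' @param spikes a `spike_record` (its oscillating population is used) or a
#'   numeric vector of spike times (ms).
#' @param t evaluation time (ms); must be at least `window_T`.
#' @param f frequency (Hz); may be a vector.
#' @param config a [phase_tracker_config()].
#' @return Complex coefficient(s) with attribute `n_window` (spike count in
#'   the window).
#' @export
weighted_fourier <- function(spikes, t, f, config = phase_tracker_config()) {
  stopifnot(length(t) == 1)
  if (t < config$window_T)
    warning("t is earlier than one full window; the fit is one-sided anyway")
  s <- spike_times(spikes)
  s <- s[s >= t - config$window_T & s <= t]
  n <- length(s)
  x <- vapply(f, function(fj) {
    if (!n) return(0 + 0i)
    sum(exp((s - t) / config$tau) * exp(-2i * pi * fj * s / 1000))
  }, complex(1))
  attr(x, "n_window") <- n
  x
}

#' Instantaneous population phase
#'
#' The angle (in cycles) of `sum_f X(f, t) exp(2 pi i t f)` over the
#' tracker's frequency grid.  Returns `NA` when no spikes fall in the
#' window (low-confidence evaluation); the attribute `valid` reports this.
#'
#' @inheritParams weighted_fourier
#' @return Phase in cycles `[0, 1)`, or `NA` if invalid.
#' @export
instantaneous_phase <- function(spikes, t, config = phase_tracker_config()) {
  freqs <- tracker_freqs(config)
  X <- weighted_fourier(spikes, t, freqs, config)
  n <- attr(X, "n_window")
  if (!n) return(structure(NA_real_, valid = FALSE))
  z <- sum(X * exp(2i * pi * freqs * t / 1000))
  structure(wrap_phase(Arg(z) / (2 * pi)), valid = TRUE)
}

#' Phase trace over a time grid
#'
#' Evaluates the online estimator on a regular grid (incremental
#' implementation; identical to calling [instantaneous_phase()] at every
#' grid point).
#'
#' @param spikes a `spike_record` or numeric spike times (ms).
#' @param config a [phase_tracker_config()].
#' @param t_start,t_end grid limits (ms); `t_start` defaults to one window,
#'   `t_end` to the last spike.
#' @return A `phase_trace` data.frame: `t`, `phi`, `valid`, `n_spikes`.
#' @export
phase_trace <- function(spikes, config = phase_tracker_config(),
                        t_start = NULL, t_end = NULL) {
  s <- spike_times(spikes)
  t_start <- t_start %||% config$window_T
  t_end <- t_end %||% (attr(spikes, "duration") %||% max(s))
  stopifnot(t_end > t_start)
  tr <- phase_trace_cpp(s, t_start, t_end, config$eval_dt,
                        tracker_freqs(config), config$tau, config$window_T)
  tr$valid <- tr$valid == 1L
  class(tr) <- c("phase_trace", "data.frame")
  attr(tr, "config") <- config
  tr
}

#' @export
print.phase_trace <- function(x, ...) {
  cat(sprintf("<phase_trace> %d evaluations, %.1f..%.1f ms, %.1f%% valid\n",
              nrow(x), min(x$t), max(x$t), 100 * mean(x$valid)))
  invisible(x)
}

#' Detect midpoint (phase = 0) crossings
#'
#' Returns the times where the estimated phase wraps from near 1 down
#' through 0, with linear sub-grid interpolation.  A refractory lockout of
#' half the nominal period suppresses double triggers caused by estimator
#' jitter; invalid evaluations never trigger.
#'
#' @param trace a `phase_trace`.
#' @param nominal_period oscillation period (ms) used for the lockout.
#' @param lockout explicit lockout (ms); default half the nominal period.
#' @return Numeric vector of trigger times (ms); empty if no crossings.
#' @export
detect_midpoint_crossings <- function(trace, nominal_period = NOMINAL_PERIOD_MS,
                                      lockout = nominal_period / 2) {
  t <- trace$t; phi <- trace$phi; ok <- trace$valid
  n <- length(t)
  if (n < 2) return(numeric(0))
  prev <- seq_len(n - 1); nxt <- prev + 1
  wrap <- ok[prev] & ok[nxt] & ((phi[prev] - phi[nxt]) > 0.5)
  idx <- which(wrap)
  if (!length(idx)) return(numeric(0))
  frac <- (1 - phi[idx]) / ((phi[idx + 1] + 1) - phi[idx])
  cand <- t[idx] + frac * (t[idx + 1] - t[idx])
  out <- numeric(0); last <- -Inf
  for (tc in cand) {
    if (tc - last >= lockout) { out <- c(out, tc); last <- tc }
  }
  out
}

#' Write a phase trace as columnar text
#' @param trace a `phase_trace`.
#' @param path output file.
#' @export
write_phase_trace <- function(trace, path) {
  df <- data.frame(t_ms = trace$t, phi_cycles = trace$phi,
                   valid = as.integer(trace$valid))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a phase trace written by [write_phase_trace()]
#' @param path input file.
#' @export
read_phase_trace <- function(path) {
  df <- read.table(path, header = TRUE)
  tr <- data.frame(t = df$t_ms, phi = df$phi_cycles, valid = df$valid == 1,
                   n_spikes = NA_integer_)
  class(tr) <- c("phase_trace", "data.frame")
  tr
}
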