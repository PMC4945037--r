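# Stimulation protocols: open-loop periodic trains, low-rate PRC probes and
# closed-loop phase-locked pulses/bursts, all expressed as stim_events.

#' Protocol configuration
#'
#' @param mode one of `"off"`, `"openloop"`, `"probe"`, `"phasic_single"`,
#'   `"phabs"`.
#' @param openloop_rate open-loop pulse rate (Hz).
#' @param probe_rate PRC probe rate (Hz).
#' @param delay delay (ms) from trigger to first pulse (sweep variable).
#' @param n_delays number of delays in a phase sweep, spanning one period.
#' @param burst_pulses pulses per burst (`phabs` and burst probes).
#' @param isi_delta inter-stimulus interval within a burst (ms).
#' @param amplitude pulse amplitude, fraction of the reference amplitude.
#' @param width pulse width (ms).
#' @param duration protocol duration (s).
#' @param volley deliver the efferent synaptic volley at each pulse
#'   (full-amplitude open-loop stimulation).
#' @return A `protocol_config` object.
#' @export
protocol_config <- function(mode = c("off", "openloop", "probe",
                                     "phasic_single", "phabs"),
                            openloop_rate = 136, probe_rate = 2, delay = 0,
                            n_delays = 10, burst_pulses = 3, isi_delta = 5,
                            amplitude = 0.1, width = 0.5, duration = 100,
                            volley = FALSE) {
  mode <- match.arg(mode)
  stopifnot(isi_delta > 0, burst_pulses >= 1, amplitude >= 0, width > 0)
  structure(list(mode = mode, openloop_rate = openloop_rate,
                 probe_rate = probe_rate, delay = delay, n_delays = n_delays,
                 burst_pulses = as.integer(burst_pulses),
                 isi_delta = isi_delta, amplitude = amplitude, width = width,
                 duration = duration, volley = volley),
            class = "protocol_config")
}

#' Schedule closed-loop pulses from trigger times
#'
#' For each trigger at `t0`, mode `"phasic_single"` emits one pulse at
#' `t0 + delay`; `"phabs"` emits `burst_pulses` pulses at
#' `t0 + delay + k * isi_delta`.  Pulses of a burst that would land at or
#' after the next trigger are truncated, preserving at most one burst per
#' oscillation cycle.
#'
#' @param triggers sorted trigger times (ms).
#' @param protocol a [protocol_config()] with mode `"phasic_single"` or
#'   `"phabs"`.
#' @param delay overrides `protocol$delay` (ms); must be non-negative.
#' @return A [stim_events()] table with one burst id per trigger.
#' @export
schedule_closed_loop <- function(triggers, protocol, delay = NULL) {
  delay <- delay %||% protocol$delay
  if (delay < 0) stop("delay must be non-negative (causal stimulation)")
  stopifnot(!is.unsorted(triggers))
  n_pulses <- if (protocol$mode == "phabs") protocol$burst_pulses else 1L
  t_on <- c(); burst <- c()
  nxt <- c(triggers[-1], Inf)
  for (i in seq_along(triggers)) {
    tt <- triggers[i] + delay + (seq_len(n_pulses) - 1) * protocol$isi_delta
    tt <- tt[tt < nxt[i]]   # truncate at the next trigger
    t_on <- c(t_on, tt)
    burst <- c(burst, rep(i, length(tt)))
  }
  stim_events(t_on, amplitude = protocol$amplitude, width = protocol$width,
              burst = burst)
}

#' Schedule an open-loop pulse train
#'
#' Uniformly spaced events over `[0, duration]`: single pulses at
#' `openloop_rate` in mode `"openloop"`, or probe events at `probe_rate` in
#' mode `"probe"` (each probe is a burst of `burst_pulses` pulses spaced
#' `isi_delta` ms; set `burst_pulses = 1` for single-pulse probes).
#'
#' @param protocol a [protocol_config()].
#' @param duration schedule length (ms).
#' @return A [stim_events()] table.
#' @export
schedule_open_loop <- function(protocol, duration) {
  mode <- protocol$mode
  stopifnot(mode %in% c("openloop", "probe"))
  rate <- if (mode == "openloop") protocol$openloop_rate else protocol$probe_rate
  stopifnot(rate > 0)
  spacing <- 1000 / rate
  n_pulses <- if (mode == "probe") protocol$burst_pulses else 1L
  if (rate / 1000 * duration * n_pulses > 5e6)
    stop("protocol would generate more than 5e6 pulses; shorten it")
  starts <- seq(spacing, duration, by = spacing)
  offs <- (seq_len(n_pulses) - 1) * protocol$isi_delta
  t_on <- rep(starts, each = n_pulses) + rep(offs, length(starts))
  keep <- t_on <= duration
  stim_events(t_on[keep],
              amplitude = protocol$amplitude, width = protocol$width,
              burst = rep(seq_along(starts), each = n_pulses)[keep])
}

#' Delays spanning one oscillation period
#'
#' @param protocol a [protocol_config()]; uses `n_delays`.
#' @param period_ms oscillation period (ms).
#' @return Numeric vector of `n_delays` delays uniformly covering one period.
#' @export
sweep_delays <- function(protocol, period_ms = NOMINAL_PERIOD_MS) {
  (seq_len(protocol$n_delays) - 1) / protocol$n_delays * period_ms
}
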