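# Simulation front-ends.  Both backends return a spike_record; extra outputs
# (delivered stimuli with estimated phases, triggers, phase trace) travel as
# attributes so downstream modules stay backend-agnostic.

cl_spec_none <- function() list(mode = "none")

#' Build the quenched structure of a network instance
#'
#' Draws the random connectivity (fixed in-degree per pathway), the
#' per-neuron tonic biases and the initial membrane potentials under the
#' configuration's `structure_seed`.  Two configurations sharing a
#' `structure_seed` (e.g. the healthy and parkinsonian regimes, or repeated
#' runs with different noise seeds) describe the same network instance.
#'
#' @param config a [network_config()].
#' @return List with edge vectors (`src`, `tgt`, `w`, `delay`, `inh`;
#'   absolute 1-based indices in STN, GPe, GPi order), `bias` and `V0`.
#' @export
build_network_structure <- function(config) {
  set.seed(config$structure_seed)
  n <- c(config$n_stn, config$n_gpe, config$n_gpi)
  off <- c(0, n[1], n[1] + n[2])          # STN, GPe, GPi offsets
  pop_of <- c(stn = 1, gpe = 2, gpi = 3)
  src <- tgt <- inh <- integer(0); w <- dly <- numeric(0)
  add <- function(path, from, to, inhibitory, no_self = FALSE) {
    nt <- n[pop_of[to]]; ns <- n[pop_of[from]]
    s <- sample.int(ns, path$K * nt, replace = TRUE)
    t <- rep(seq_len(nt), each = path$K)
    if (no_self) {
      same <- s == t
      while (any(same)) {
        s[same] <- sample.int(ns, sum(same), replace = TRUE)
        same <- s == t
      }
    }
    src <<- c(src, s + off[pop_of[from]])
    tgt <<- c(tgt, t + off[pop_of[to]])
    w <<- c(w, rep(path$w, length(s)))
    dly <<- c(dly, rep(path$delay, length(s)))
    inh <<- c(inh, rep(as.integer(inhibitory), length(s)))
  }
  cp <- config$coupling
  add(cp$stn_gpe, "stn", "gpe", FALSE)
  add(cp$gpe_stn, "gpe", "stn", TRUE)
  add(cp$stn_gpi, "stn", "gpi", FALSE)
  add(cp$gpe_gpi, "gpe", "gpi", TRUE)
  add(cp$gpe_gpe, "gpe", "gpe", TRUE, no_self = TRUE)
  nn <- config$neuron
  pop_idx <- rep(1:3, n)
  bias <- nn$bias_mean[pop_idx] + nn$bias_sd[pop_idx] * rnorm(sum(n))
  V0 <- nn$E_leak + runif(sum(n)) * (nn$V_thresh - nn$E_leak)
  list(src = src, tgt = tgt, w = w, delay = dly, inh = inh,
       bias = bias, V0 = V0)
}

cl_spec <- function(mode, tracker, record_trace = FALSE, lockout = NULL,
                    delay = 0, isi = 5, n_pulses = 1, amp = 0.1, width = 0.5,
                    volley = FALSE, deadlock_ms = 1000) {
  freqs <- seq(tracker$f_min, tracker$f_max, by = tracker$f_step)
  f_mid <- mean(range(freqs))
  list(mode = mode, freqs = freqs, tau = tracker$tau, T = tracker$window_T,
       eval_dt = tracker$eval_dt, start = tracker$window_T,
       lockout = lockout %||% (1000 / f_mid / 2),
       deadlock_ms = deadlock_ms, record_trace = record_trace,
       delay = delay, isi = isi, n_pulses = as.integer(n_pulses),
       amp = amp, width = width, volley = volley)
}

finish_run <- function(raw, config, duration, backend, osc_population) {
  pops <- POPULATIONS
  if (backend == "network") {
    pop <- pops[raw$pop + 1L]
    sp <- spike_record(pop, raw$neuron, raw$t, osc_population = osc_population,
                       duration = duration)
  } else {
    sp <- spike_record(rep("OSC", length(raw$t)), raw$neuron, raw$t,
                       osc_population = "OSC", duration = duration)
    attr(sp, "phases_end") <- raw$phases_end
  }
  if (length(raw$stim_t)) {
    st <- stim_events(raw$stim_t, raw$stim_amp, raw$stim_width,
                      target = if (backend == "network") "STN" else "OSC",
                      burst = cumsum(raw$stim_k[order(raw$stim_t)] == 0),
                      phase = if (length(raw$stim_phase)) raw$stim_phase[order(raw$stim_t)] else NA_real_)
    attr(sp, "stim") <- st
  } else attr(sp, "stim") <- stim_events(numeric(0))
  attr(sp, "triggers") <- raw$triggers
  if (!is.null(raw$trace)) {
    tr <- raw$trace
    tr$valid <- tr$valid == 1L
    class(tr) <- c("phase_trace", "data.frame")
    attr(sp, "trace") <- tr
  }
  attr(sp, "backend") <- backend
  attr(sp, "config") <- config
  sp
}

#' Simulate the spiking-network surrogate
#'
#' Runs the STN/GPe/GPi surrogate for `duration` ms, optionally injecting a
#' predefined list of stimulus pulses (rectangular current into every STN
#' neuron; at full amplitude an efferent synaptic volley to GPe/GPi can be
#' enabled).  In the parkinsonian regime an emergent beta-band (~34 Hz)
#' population oscillation appears in GPe; in the healthy regime only the
#' 16 Hz cortical drive is visible.
#'
#' @param config a [network_config()].
#' @param duration simulated time (ms); at least one oscillation cycle.
#' @param stim optional [stim_events()] to inject (sorted by onset).
#' @param volley deliver an efferent synaptic volley to GPe/GPi at each pulse
#'   (full-amplitude open-loop mode).
#' @param tracker optional [phase_tracker_config()]; when supplied the online
#'   phase estimator runs alongside the simulation, recording triggers and
#'   the estimated phase at each pulse onset (no stimulation is generated).
#' @param record_trace keep the full phase trace (requires `tracker`).
#' @return A `spike_record` with attributes `stim`, `triggers`, `trace`.
#' @export
simulate_network <- function(config, duration, stim = NULL, volley = FALSE,
                             tracker = NULL, record_trace = FALSE) {
  stopifnot(inherits(config, "network_config"))
  if (duration < NOMINAL_PERIOD_MS)
    stop("duration shorter than one oscillation cycle")
  if (!is.null(stim) && nrow(stim) && (min(stim$t_on) < 0 || max(stim$t_on) > duration))
    stop("stim events must lie within [0, duration]")
  cl <- if (is.null(tracker)) cl_spec_none() else
    cl_spec("track", tracker, record_trace = record_trace, deadlock_ms = 0)
  struct <- build_network_structure(config)
  set.seed(config$seed)
  raw <- sim_network_cpp(as_engine_config(config), duration,
                         as_stim_matrix(stim, volley), cl, struct)
  finish_run(raw, config, duration, "network", "GPe")
}

#' Simulate a population of phase oscillators
#'
#' Each oscillator advances at `1/natural_period` cycles per ms, emits a
#' spike when its phase wraps through 1, receives Gaussian per-cycle jitter,
#' and is advanced by `prc_fn(phase) * amplitude / amp_ref` at each stimulus
#' pulse.  Serves as an analytic oracle for PRC-based predictions.
#'
#' @param config a [phase_oscillator_config()].
#' @param duration simulated time (ms).
#' @param stim optional [stim_events()].
#' @param tracker,record_trace as in [simulate_network()].
#' @param initial_phases optional explicit initial phases (cycles),
#'   overriding the seeded draw.
#' @return A `spike_record` (population `"OSC"`) with attribute
#'   `phases_end` holding the final phases.
#' @export
simulate_phase_population <- function(config, duration, stim = NULL,
                                      tracker = NULL, record_trace = FALSE,
                                      initial_phases = NULL) {
  stopifnot(inherits(config, "phase_oscillator_config"))
  set.seed(config$seed)
  phases <- initial_phases %||% (
    if (is.infinite(config$initial_spread)) runif(config$n_osc) else
      wrap_phase(rnorm(config$n_osc, 0, config$initial_spread)))
  cfg <- list(phases = phases, period = config$natural_period,
              jitter_sd = config$phase_noise_sd, prc = config$prc,
              amp_ref = config$amp_ref)
  cl <- if (is.null(tracker)) cl_spec_none() else
    cl_spec("track", tracker, record_trace = record_trace, deadlock_ms = 0)
  raw <- sim_phasepop_cpp(cfg, duration, as_stim_matrix(stim), cl)
  finish_run(raw, config, duration, "phase_population", "OSC")
}

#' Run a closed-loop protocol on either backend
#'
#' Couples the online phase tracker to the simulator: every `eval_dt` the
#' tracker updates from already-emitted oscillation-population spikes; a wrap
#' of the estimated phase through 0 (with a half-period lockout) triggers a
#' pulse (or burst) after `delay` ms.  Pulses from a burst still pending when
#' the next trigger arrives are truncated.
#'
#' @param config a [network_config()] or [phase_oscillator_config()].
#' @param duration simulated time (ms).
#' @param protocol a [protocol_config()] with mode `"phasic_single"`,
#'   `"phabs"`, `"openloop"`, `"probe"` or `"off"`.
#' @param delay delay (ms) from trigger to first pulse; overrides
#'   `protocol$delay`.
#' @param tracker a [phase_tracker_config()].
#' @param record_trace keep the full phase trace.
#' @param deadlock_s abort when no trigger occurs for this many seconds
#'   (diagnostic for a stalled loop); 0 disables the check, e.g. for
#'   uncoupled phase populations that stimulation fully desynchronizes so
#'   that the oscillation -- and with it the triggering -- legitimately
#'   dies.
#' @return A `spike_record` with attributes `stim`, `triggers`, `trace`.
#' @export
run_protocol <- function(config, duration, protocol, delay = NULL,
                         tracker = phase_tracker_config(),
                         record_trace = FALSE, deadlock_s = 1) {
  mode <- protocol$mode
  delay <- delay %||% protocol$delay
  if (mode %in% c("off", "openloop", "probe")) {
    stim <- if (mode == "off") NULL else schedule_open_loop(protocol, duration)
    volley <- isTRUE(protocol$volley)
    if (inherits(config, "network_config"))
      return(simulate_network(config, duration, stim, volley = volley,
                              tracker = tracker, record_trace = record_trace))
    return(simulate_phase_population(config, duration, stim, tracker = tracker,
                                     record_trace = record_trace))
  }
  if (delay < 0) stop("delay must be non-negative (causal stimulation)")
  n_pulses <- if (mode == "phabs") protocol$burst_pulses else 1L
  cl <- cl_spec("stim", tracker, record_trace = record_trace,
                delay = delay, isi = protocol$isi_delta, n_pulses = n_pulses,
                amp = protocol$amplitude, width = protocol$width,
                volley = isTRUE(protocol$volley),
                deadlock_ms = deadlock_s * 1000)
  if (inherits(config, "network_config")) {
    struct <- build_network_structure(config)
    set.seed(config$seed)
    raw <- sim_network_cpp(as_engine_config(config), duration,
                           as_stim_matrix(NULL), cl, struct)
    return(finish_run(raw, config, duration, "network", "GPe"))
  }
  set.seed(config$seed)
  phases <- if (is.infinite(config$initial_spread)) runif(config$n_osc) else
    wrap_phase(rnorm(config$n_osc, 0, config$initial_spread))
  cfg <- list(phases = phases, period = config$natural_period,
              jitter_sd = config$phase_noise_sd, prc = config$prc,
              amp_ref = config$amp_ref)
  raw <- sim_phasepop_cpp(cfg, duration, as_stim_matrix(NULL), cl)
  finish_run(raw, config, duration, "phase_population", "OSC")
}

#' Calibrate the reference stimulation amplitude
#'
#' The reference ("clinical") amplitude is defined as the smallest pulse
#' amplitude that entrains STN firing at 136 Hz: at least `target` of STN
#' spikes (default: a majority) fall within `window_ms` after a pulse.  The
#' shipped configuration stores the calibrated value as `stim$ref_amp`;
#' this function reproduces the calibration.
#'
#' @param config a [network_config()].
#' @param amps candidate amplitudes (multiples of the configured `ref_amp`).
#' @param duration test duration per amplitude (ms).
#' @param window_ms entrainment window after each pulse.
#' @param target required entrained fraction of STN spikes.
#' @return data.frame of amplitude fraction vs entrained fraction, with the
#'   smallest entraining amplitude in `attr(, "reference")`.
#' @export
calibrate_reference_amplitude <- function(config, amps = c(0.25, 0.5, 0.75, 1, 1.5, 2),
                                          duration = 2000, window_ms = 2,
                                          target = 0.5) {
  period <- 1000 / 136
  res <- vapply(amps, function(a) {
    st <- stim_events(seq(period, duration - 1, by = period), amplitude = a)
    sp <- simulate_network(config, duration, st, volley = FALSE)
    ts <- spike_times(sp, "STN")
    ts <- ts[ts > 500]
    if (!length(ts)) return(0)
    lag <- (ts - period) %% period
    mean(lag <= window_ms)
  }, numeric(1))
  out <- data.frame(amplitude = amps, entrained = res)
  hit <- which(res >= target)
  attr(out, "reference") <- if (length(hit)) amps[min(hit)] else NA_real_
  out
}
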