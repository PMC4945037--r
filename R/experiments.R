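# Orchestration of the in-silico experiments: baseline spectra, PRC
# measurement (single-pulse and burst probes), closed-loop phase sweeps, and
# prediction-vs-simulation comparison.

#' Experiment specification
#'
#' @param name identifier recorded in outputs.
#' @param backend `"network"` or `"phase_population"`.
#' @param config backend configuration template ([network_config()] or
#'   [phase_oscillator_config()]); the per-run seed is substituted.
#' @param protocol a [protocol_config()].
#' @param tracker a [phase_tracker_config()].
#' @param n_seeds number of seeds (1..n unless `seeds` given).
#' @param seeds explicit seed vector.
#' @param duration_s per-run duration in seconds (before scaling).
#' @param scale factor in (0, 1] applied to duration and to network
#'   population sizes for desk-scale runs.
#' @param f0 oscillation frequency (Hz); `NULL` = measured from the run.
#' @param period_ms oscillation period (ms) for delay placement.
#' @return An `experiment_spec` object.
#' @export
experiment_spec <- function(name = "experiment",
                            backend = c("network", "phase_population"),
                            config = NULL, protocol = protocol_config("phabs"),
                            tracker = phase_tracker_config(), n_seeds = 3,
                            seeds = NULL, duration_s = 20, scale = 1,
                            f0 = NULL, period_ms = NOMINAL_PERIOD_MS) {
  backend <- match.arg(backend)
  stopifnot(scale > 0, scale <= 1)
  config <- config %||% (if (backend == "network") network_config() else
    phase_oscillator_config())
  structure(list(name = name, backend = backend, config = config,
                 protocol = protocol, tracker = tracker,
                 seeds = seeds %||% seq_len(n_seeds),
                 duration_s = duration_s, scale = scale, f0 = f0,
                 period_ms = period_ms),
            class = "experiment_spec")
}

spec_config <- function(spec, seed) {
  cfg <- spec$config
  cfg$seed <- as.integer(seed)
  if (spec$backend == "network" && spec$scale < 1) {
    cfg$n_stn <- max(10L, as.integer(round(cfg$n_stn * spec$scale)))
    cfg$n_gpe <- max(10L, as.integer(round(cfg$n_gpe * spec$scale)))
    cfg$n_gpi <- max(10L, as.integer(round(cfg$n_gpi * spec$scale)))
  }
  cfg
}

spec_duration_ms <- function(spec) spec$duration_s * spec$scale * 1000

run_one <- function(spec, seed, mode, delay = 0, record_trace = FALSE) {
  cfg <- spec_config(spec, seed)
  proto <- spec$protocol
  proto$mode <- mode
  run_protocol(cfg, spec_duration_ms(spec), proto, delay = delay,
               tracker = spec$tracker, record_trace = record_trace)
}

#' Measure the emergent oscillation frequency of a configuration
#'
#' Runs the backend without stimulation and reports the spectral peak of the
#' oscillating population in `band`.
#'
#' @param config backend configuration.
#' @param duration_ms run length (ms).
#' @param band search band (Hz).
#' @return Peak frequency (Hz), with the `spectral_summary` as attribute.
#' @export
measure_oscillation_frequency <- function(config, duration_ms = 10000,
                                          band = c(20, 60)) {
  sp <- if (inherits(config, "network_config"))
    simulate_network(config, duration_ms) else
      simulate_phase_population(config, duration_ms)
  spec <- population_spectrum(sp)
  structure(peak_frequency(spec, band), spectrum = spec)
}

#' Run a closed-loop phase sweep
#'
#' One stimulation-off run and one closed-loop run per delay, per seed, on
#' matched seeds; delays span one nominal period uniformly.  The outcome is
#' the percent change of the beta/gamma power ratio versus the off run.
#'
#' @param spec an [experiment_spec()] whose protocol mode is
#'   `"phasic_single"` or `"phabs"`.
#' @param off_ratios optional named numeric vector of stimulation-off
#'   beta/gamma ratios keyed by seed (as from [sweep_off_ratios()]); when
#'   two sweeps share seeds and configuration, computing the off runs once
#'   halves the baseline cost.
#' @return A `phase_sweep` data.frame: `delay`, `mean_phase`, `pct_change`
#'   (mean over seeds), `sd`, `ci_lo`, `ci_hi`; per-seed values in
#'   `attr(, "per_seed")`.
#' @export
run_phase_sweep <- function(spec, off_ratios = NULL) {
  stopifnot(spec$protocol$mode %in% c("phasic_single", "phabs"))
  delays <- sweep_delays(spec$protocol, spec$period_ms)
  seeds <- spec$seeds
  pct <- matrix(NA_real_, length(delays), length(seeds))
  phase <- matrix(NA_real_, length(delays), length(seeds))
  for (j in seq_along(seeds)) {
    ratio_off <- off_ratios[[as.character(seeds[j])]]
    if (is.null(ratio_off) || is.na(ratio_off)) {
      off <- run_one(spec, seeds[j], "off")
      ratio_off <- population_spectrum(off)$beta_gamma_ratio
    }
    for (i in seq_along(delays)) {
      r <- run_one(spec, seeds[j], spec$protocol$mode, delay = delays[i])
      ratio <- population_spectrum(r)$beta_gamma_ratio
      pct[i, j] <- 100 * (ratio - ratio_off) / ratio_off
      st <- attr(r, "stim")
      if (!is.null(st) && nrow(st)) {
        p <- st$phase[!duplicated(st$burst)]
        p <- p[!is.na(p)]
        if (length(p)) phase[i, j] <- circ_mean(p, positive = TRUE)
      }
    }
  }
  m <- rowMeans(pct)
  s <- apply(pct, 1, sd)
  n <- length(seeds)
  tq <- if (n > 1) qt(0.975, n - 1) else NA_real_
  mp <- apply(phase, 1, function(p) {
    p <- p[!is.na(p)]
    if (length(p)) circ_mean(p, positive = TRUE) else NA_real_
  })
  out <- data.frame(delay = delays, mean_phase = mp, pct_change = m, sd = s,
                    ci_lo = m - tq * s / sqrt(n), ci_hi = m + tq * s / sqrt(n))
  class(out) <- c("phase_sweep", "data.frame")
  attr(out, "per_seed") <- pct
  attr(out, "seeds") <- seeds
  attr(out, "mode") <- spec$protocol$mode
  out
}

#' Stimulation-off beta/gamma ratios for a sweep's seeds
#'
#' @param spec an [experiment_spec()].
#' @return Named numeric vector of off-run ratios keyed by seed, for
#'   [run_phase_sweep()]'s `off_ratios`.
#' @export
sweep_off_ratios <- function(spec) {
  out <- vapply(spec$seeds, function(s)
    population_spectrum(run_one(spec, s, "off"))$beta_gamma_ratio, numeric(1))
  names(out) <- as.character(spec$seeds)
  out
}

#' Best suppression of a phase sweep
#'
#' @param sweep a `phase_sweep`.
#' @return Percent reduction (positive number) at the best delay.
#' @export
best_reduction <- function(sweep) -min(sweep$pct_change)

#' Measure a population PRC with low-rate probes
#'
#' Runs the backend with 2 Hz probe events (single pulses, or bursts of
#' `pulses` for the burst PRC) while the online tracker records the phase at
#' each probe onset, then bins the pre/post Fourier phase advances.
#'
#' @param spec an [experiment_spec()]; its protocol supplies probe rate,
#'   amplitude and inter-pulse interval.
#' @param pulses 1 or 3 pulses per probe burst.
#' @param n_bins phase bins.
#' @param seed which seed to use (default: first of the spec).
#' @return A `prc_estimate` with attribute `f0` (the oscillation frequency
#'   used for the advance fit, measured from the run's spectral peak when
#'   the spec does not fix it).
#' @export
run_prc_experiment <- function(spec, pulses = 1, n_bins = 16, seed = NULL) {
  cfg <- spec_config(spec, seed %||% spec$seeds[1])
  proto <- spec$protocol
  proto$mode <- "probe"
  proto$burst_pulses <- as.integer(pulses)
  run <- run_protocol(cfg, spec_duration_ms(spec), proto,
                      tracker = spec$tracker)
  f0 <- spec$f0 %||% estimate_f0(run)
  st <- attr(run, "stim")
  # drop probes inside the tracker warm-up (no phase estimate there)
  keep <- st$t_on >= spec$tracker$window_T + 100
  st <- st[keep, , drop = FALSE]
  class(st) <- c("stim_events", "data.frame")
  estimate_prc(run, st, n_bins = n_bins, pulses_per_burst = pulses,
               config = spec$tracker, f0 = f0)
}

#' Compare PRC-based predictions with a measured phase sweep
#'
#' Predicted separation growth above 1 marks desynchronizing
#' (oscillation-suppressing) phases; the comparison scores per-delay sign
#' agreement between prediction and the measured percent change, plus the
#' Spearman rank correlation between predicted growth and measured
#' suppression.
#'
#' @param prc a `prc_estimate` (or [prc_function()]).
#' @param sweep a `phase_sweep`.
#' @param pulses pulses per burst used in the sweep.
#' @param delta_ms inter-stimulus interval of the burst (ms).
#' @param period_ms oscillation period (ms).
#' @param harmonics smoothing harmonics.
#' @return List: `agreement` (fraction), `n_agree`, `n`, `rho`, and the
#'   per-delay `table`.
#' @export
compare_prediction_to_sweep <- function(prc, sweep, pulses = 1, delta_ms = 5,
                                        period_ms = NOMINAL_PERIOD_MS,
                                        harmonics = 4) {
  Zf <- prc_function(prc, harmonics = harmonics)
  phi <- sweep$mean_phase
  growth <- abs(divergence_burst(phi = phi, delta = delta_ms / period_ms,
                                 eps = 1, Zs = rep(list(Zf), pulses)))
  ok <- !is.na(phi) & !is.na(sweep$pct_change)
  agree <- (growth > 1) == (sweep$pct_change < 0)
  tab <- data.frame(delay = sweep$delay, phase = phi, growth = growth,
                    pct_change = sweep$pct_change, agree = agree)
  list(agreement = mean(agree[ok]), n_agree = sum(agree[ok]), n = sum(ok),
       rho = suppressWarnings(cor(growth[ok], -sweep$pct_change[ok],
                                  method = "spearman")),
       table = tab)
}
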