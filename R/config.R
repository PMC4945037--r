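# Configuration: a single YAML file holds every default.  The shipped file
# is the canonical tuned parameter set; users may load and edit a copy.

the <- new.env(parent = emptyenv())

#' Path to the shipped default configuration file
#' @export
default_config_path <- function() {
  system.file("extdata", "default_config.yaml", package = "phabs")
}

#' Load a configuration file
#'
#' @param path YAML configuration; defaults to the shipped file.
#' @return Nested named list.
#' @export
read_config <- function(path = default_config_path()) {
  yaml::read_yaml(path)
}

default_config <- function() {
  if (is.null(the$config)) the$config <- read_config()
  the$config
}

# recursive modifyList that tolerates NULL
merge_config <- function(base, override) {
  if (is.null(override)) return(base)
  modifyList(base, override)
}

#' Network configuration
#'
#' Builds the full parameter set of the spiking-network surrogate.  The
#' `parkinsonian` regime applies the override table from the configuration
#' file (stronger STN<->GPe coupling and increased striatal inhibition of
#' GPe); all other parameters are shared between regimes.
#'
#' @param regime `"parkinsonian"` or `"healthy"`.
#' @param seed integer RNG seed for the run noise (input spike trains,
#'   per-cycle gains); fixed seed gives bitwise-identical spikes.
#' @param structure_seed integer seed for the quenched structure
#'   (connectivity draws, per-neuron biases, initial conditions).  Kept
#'   separate from `seed` so that repeated runs with different noise
#'   realizations probe the same network instance, as repeated stimulation
#'   sessions in one subject would.
#' @param n_stn,n_gpe,n_gpi population sizes.
#' @param dt integration step (ms).
#' @param config base configuration list (defaults to the shipped file).
#' @param ... named overrides merged into the network section, e.g.
#'   `coupling = list(stn_gpe = list(w = 0.1))`.
#' @return A `network_config` object.
#' @export
network_config <- function(regime = c("parkinsonian", "healthy"), seed = 1,
                           structure_seed = 42, n_stn = NULL, n_gpe = NULL,
                           n_gpi = NULL, dt = NULL,
                           config = default_config(), ...) {
  regime <- match.arg(regime)
  net <- config$network
  pd <- net$parkinsonian
  net$parkinsonian <- NULL
  if (regime == "parkinsonian") net <- merge_config(net, pd)
  net <- merge_config(net, list(...))
  if (!is.null(n_stn)) net$n_stn <- n_stn
  if (!is.null(n_gpe)) net$n_gpe <- n_gpe
  if (!is.null(n_gpi)) net$n_gpi <- n_gpi
  if (!is.null(dt)) net$dt <- dt
  stopifnot(net$n_stn > 0, net$n_gpe > 0, net$n_gpi > 0, net$dt > 0)
  net$regime <- regime
  net$seed <- as.integer(seed)
  net$structure_seed <- as.integer(structure_seed)
  structure(net, class = "network_config")
}

#' @export
print.network_config <- function(x, ...) {
  cat(sprintf("<network_config> regime=%s  GPe/STN/GPi=%d/%d/%d  dt=%g ms  seed=%d\n",
              x$regime, x$n_gpe, x$n_stn, x$n_gpi, x$dt, x$seed))
  invisible(x)
}

# flatten a network_config into the list the C++ engine expects
as_engine_config <- function(config) {
  nn <- config$neuron
  list(n_stn = as.integer(config$n_stn), n_gpe = as.integer(config$n_gpe),
       n_gpi = as.integer(config$n_gpi), dt = config$dt,
       E_leak = nn$E_leak, E_exc = nn$E_exc, E_inh = nn$E_inh,
       V_thresh = nn$V_thresh, V_reset = nn$V_reset, t_ref = nn$t_ref,
       tau_exc = nn$tau_exc, tau_inh = nn$tau_inh,
       tau_m = as.numeric(nn$tau_m), bias_mean = as.numeric(nn$bias_mean),
       bias_sd = as.numeric(nn$bias_sd),
       coupling = config$coupling,
       cortical_drive = config$cortical_drive,
       striatal_drive = config$striatal_drive,
       background = config$background,
       stim = config$stim)
}

#' Phase-oscillator population configuration
#'
#' An analytic backend in which each unit is a phase oscillator with a known
#' phase response curve, used as an oracle for the prediction theory.
#'
#' @param n_osc number of oscillators.
#' @param natural_period oscillation period (ms).
#' @param prc_fn the generative PRC: a function of phase in cycles on
#'   `[0, 1)` returning the phase advance (cycles) of one pulse at the
#'   reference probe amplitude `amp_ref`, or a numeric vector sampling it on
#'   a uniform grid.
#' @param phase_noise_sd per-cycle phase jitter (cycles) applied at each wrap.
#' @param initial_spread circular dispersion (cycles) of initial phases;
#'   `Inf` draws them uniformly.
#' @param seed integer RNG seed.
#' @param amp_ref amplitude at which `prc_fn` applies; kicks scale linearly
#'   as `amplitude / amp_ref`.  Set to 0 to disable amplitude scaling.
#' @param prc_grid_n grid resolution used to tabulate `prc_fn`.
#' @return A `phase_oscillator_config` object.
#' @export
phase_oscillator_config <- function(n_osc = 100, natural_period = NOMINAL_PERIOD_MS,
                                    prc_fn = function(phi) 0 * phi,
                                    phase_noise_sd = 0.005,
                                    initial_spread = 0.05, seed = 1,
                                    amp_ref = 0.1, prc_grid_n = 1024) {
  stopifnot(natural_period > 0, n_osc > 0)
  if (is.function(prc_fn)) {
    grid <- (seq_len(prc_grid_n) - 1) / prc_grid_n
    prc <- prc_fn(grid)
  } else prc <- as.numeric(prc_fn)
  if (any(!is.finite(prc))) stop("prc_fn must be finite on [0, 1)")
  structure(list(n_osc = as.integer(n_osc), natural_period = natural_period,
                 prc = prc, phase_noise_sd = phase_noise_sd,
                 initial_spread = initial_spread, seed = as.integer(seed),
                 amp_ref = amp_ref),
            class = "phase_oscillator_config")
}

#' @export
print.phase_oscillator_config <- function(x, ...) {
  cat(sprintf("<phase_oscillator_config> n=%d  period=%.2f ms  jitter=%g  seed=%d\n",
              x$n_osc, x$natural_period, x$phase_noise_sd, x$seed))
  invisible(x)
}
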