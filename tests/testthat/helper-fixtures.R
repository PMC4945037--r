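# Fixtures built in code: synthetic spike trains and analytic PRCs.

# perfect periodic comb of population spikes (one neuron), times in ms
make_comb <- function(freq_hz = 34, t_end = 3000, t0 = 0) {
  seq(t0, t_end, by = 1000 / freq_hz)
}

comb_record <- function(times, population = "GPe") {
  spike_record(rep(population, length(times)), rep(1L, length(times)), times,
               osc_population = population, duration = max(times))
}

# Poisson spikes at mean aggregate rate `rate_hz`, rate-modulated at `f_mod`
# Hz into per-cycle packets (von Mises profile, concentration `kappa`) with
# phase offset `phi0` in cycles -- the packeted discharge the spike-phase
# estimator is designed for.  Thinning; deterministic under set.seed.
modulated_poisson <- function(rate_hz = 300, f_mod = 34, kappa = 8,
                              t_end = 5000, phi0 = 0) {
  peak <- exp(kappa) / besselI(kappa, 0)
  rmax <- rate_hz * peak / 1000
  n <- stats::rpois(1, rmax * t_end)
  tt <- sort(stats::runif(n, 0, t_end))
  lam <- exp(kappa * cos(2 * pi * (f_mod * tt / 1000 - phi0))) /
    besselI(kappa, 0) / peak
  tt[stats::runif(n) < lam]
}

sin_prc <- function(a = 0.05) function(phi) a * sin(2 * pi * phi)

# analytic two-oscillator burst experiment: phases kicked by `zfun` (exact
# generative PRC), drifting `delta` cycles between kicks; returns final
# separation / eps
brute_burst_growth <- function(zfun, phi, delta, eps, pulses = 3) {
  a <- phi; b <- phi + eps
  for (k in seq_len(pulses)) {
    a <- a + zfun(a %% 1)
    b <- b + zfun(b %% 1)
    if (k < pulses) { a <- a + delta; b <- b + delta }
  }
  (b - a) / eps
}
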