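# The phase-oscillator backend: exact null cases, first-order separation
# growth, determinism.

test_that("null PRC leaves spike times identical to the stim-free run", {
  cfg <- phase_oscillator_config(n_osc = 20, prc_fn = function(p) 0 * p,
                                 phase_noise_sd = 0.002, seed = 5)
  st <- stim_events(seq(100, 900, by = 100), amplitude = 0.1)
  a <- simulate_phase_population(cfg, 1000, stim = st)
  b <- simulate_phase_population(cfg, 1000)
  # identical per-oscillator spike trains (up to float roundoff from the
  # zero-effect kick bookkeeping)
  ta <- split(a$t, a$neuron); tb <- split(b$t, b$neuron)
  expect_equal(lengths(ta), lengths(tb))
  expect_equal(ta, tb, tolerance = 1e-9)
})

test_that("a fully synchronous noise-free population stays synchronous", {
  cfg <- phase_oscillator_config(n_osc = 100, phase_noise_sd = 0,
                                 prc_fn = sin_prc(0.05), seed = 1)
  sp <- simulate_phase_population(cfg, 500, initial_phases = rep(0.25, 100))
  byn <- split(sp$t, sp$neuron)
  expect_true(all(lengths(byn) == length(byn[[1]])))
  m <- do.call(rbind, byn)
  expect_lt(max(apply(m, 2, function(x) diff(range(x)))), 1e-9)
})

test_that("one pulse grows a small separation by 1 + Z'(phi) to first order", {
  period <- 29.4
  eps <- 1e-4
  zfun <- sin_prc(0.05)
  for (phi in c(0.1, 0.35, 0.8)) {
    # pulse when oscillator 1 sits at `phi`: start both just before a pulse
    cfg <- phase_oscillator_config(n_osc = 2, natural_period = period,
                                   prc_fn = zfun, phase_noise_sd = 0,
                                   amp_ref = 0.1, seed = 1)
    t_pulse <- 50
    phi0 <- wrap_phase(phi - t_pulse / period)
    sp <- simulate_phase_population(cfg, 60,
                                    stim = stim_events(t_pulse, amplitude = 0.1),
                                    initial_phases = c(phi0, phi0 + eps))
    sep <- diff(attr(sp, "phases_end"))
    expect_equal(sep / eps, 1 + prc_slope(prc_function(zfun), phi),
                 tolerance = 1e-2)
  }
})

test_that("stimulus amplitude scales the kick linearly", {
  period <- 29.4
  zfun <- function(p) rep(0.04, length(p))
  base <- phase_oscillator_config(n_osc = 1, natural_period = period,
                                  prc_fn = zfun, phase_noise_sd = 0,
                                  amp_ref = 0.1, seed = 1)
  out <- lapply(c(0.05, 0.1), function(a) {
    sp <- simulate_phase_population(base, 40,
                                    stim = stim_events(20, amplitude = a),
                                    initial_phases = 0.2)
    attr(sp, "phases_end")
  })
  drift_end <- wrap_phase(0.2 + 40 / period)
  kick1 <- out[[1]] - drift_end
  kick2 <- out[[2]] - drift_end
  expect_equal(kick2 / kick1, 2, tolerance = 1e-9)
})

test_that("phase backend is deterministic under a fixed seed", {
  cfg <- phase_oscillator_config(n_osc = 30, prc_fn = sin_prc(0.03), seed = 9)
  a <- simulate_phase_population(cfg, 2000)
  b <- simulate_phase_population(cfg, 2000)
  expect_identical(a$t, b$t)
})

test_that("non-finite PRC values are rejected", {
  expect_error(phase_oscillator_config(prc_fn = function(p) p / 0),
               "finite")
})
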