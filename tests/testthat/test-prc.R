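# PRC estimation: null cases, constructed shifts, and parameter recovery of
# a known generative PRC on the phase-oscillator backend.

test_that("phase advance is zero for an unperturbed oscillation", {
  comb <- comb_record(make_comb(34, 2000))
  f0 <- 34
  adv <- phase_advance(comb, stim_time = 1000, f0 = f0)
  expect_equal(adv, 0, tolerance = 1e-9)
})

test_that("a time-advanced post-stimulus comb reads as a positive advance", {
  period <- 1000 / 34
  pre <- seq(0, 1000, by = period)
  post <- seq(1000 + period, 2000, by = period) - 0.1 * period
  sp <- comb_record(c(pre, post))
  adv <- phase_advance(sp, stim_time = 1000, f0 = 34)
  expect_equal(adv, 0.1, tolerance = 1e-6)
  # delayed comb: negative advance
  sp2 <- comb_record(c(pre, post + 0.2 * period))
  expect_equal(phase_advance(sp2, stim_time = 1000, f0 = 34), -0.1,
               tolerance = 1e-6)
})

test_that("stimulus phase assignment follows the comb's origin", {
  comb <- make_comb(34, 3000)
  p_on <- stim_phase(comb_record(comb), comb[40])
  p_mid <- stim_phase(comb_record(comb), comb[40] + 0.5 * 1000 / 34)
  # the multi-frequency fit advances slightly below 34 cycles/s in-cycle,
  # so mid-cycle reads just under half a cycle after onset
  expect_equal(wrap_phase(p_mid - p_on), 0.5, tolerance = 0.05)
})

test_that("empty windows exclude the stimulus rather than inventing a value", {
  comb <- comb_record(make_comb(34, 900))
  expect_true(is.na(phase_advance(comb, stim_time = 950, f0 = 34)))
})

# -- parameter recovery on the phase backend -------------------------------

recover_prc <- function(amp, n_probes = 500, a = 0.05, seed = 2) {
  period <- 29.4
  cfg <- phase_oscillator_config(n_osc = 100, natural_period = period,
                                 prc_fn = sin_prc(a), phase_noise_sd = 0,
                                 amp_ref = 0.1, seed = seed)
  set.seed(seed)
  t_on <- sort(500 + cumsum(runif(n_probes, 400, 600)))
  st <- stim_events(t_on, amplitude = amp)
  sp <- simulate_phase_population(cfg, max(t_on) + 500, stim = st,
                                  initial_phases = rep(0, cfg$n_osc))
  # generative phase oracle: linear drift plus the applied kicks
  phi <- 0; t_prev <- 0
  gen <- numeric(n_probes)
  for (k in seq_len(n_probes)) {
    phi <- phi + (t_on[k] - t_prev) / period
    gen[k] <- wrap_phase(phi)
    phi <- phi + (amp / 0.1) * 0.05 * sin(2 * pi * gen[k])
    t_prev <- t_on[k]
  }
  st$phase <- gen
  estimate_prc(sp, st, n_bins = 16, pulses_per_burst = 1, f0 = 1000 / period)
}

test_that("binned advances recover a generative sinusoid PRC", {
  prc <- recover_prc(amp = 0.1)
  ok <- prc$count >= 3
  expect_gt(sum(ok), 12)
  err <- prc$mean_advance[ok] - 0.05 * sin(2 * pi * prc$bin_center[ok])
  expect_lt(sqrt(mean(err^2)), 0.01)
})

test_that("halving the probe amplitude roughly halves the mean advances", {
  full <- recover_prc(amp = 0.1, n_probes = 300)
  half <- recover_prc(amp = 0.05, n_probes = 300)
  ok <- full$count >= 3 & half$count >= 3 &
    abs(full$mean_advance) > 0.015
  ratio <- half$mean_advance[ok] / full$mean_advance[ok]
  expect_true(all(ratio > 0.3 & ratio < 0.7))
})

test_that("sham (zero-amplitude) probes give a PRC indistinguishable from zero", {
  prc <- recover_prc(amp = 0)
  ok <- prc$count > 0
  expect_true(all(abs(prc$mean_advance[ok]) <=
                    pmax(2 * prc$circ_std[ok], 1e-6)))
})

test_that("estimates are invariant to rotating the phase origin", {
  prc <- recover_prc(amp = 0.1, n_probes = 300)
  # rebuild with phases rotated by exactly 4 bins (0.25 cycles)
  period <- 29.4
  cfg <- phase_oscillator_config(n_osc = 100, natural_period = period,
                                 prc_fn = sin_prc(), phase_noise_sd = 0,
                                 amp_ref = 0.1, seed = 2)
  set.seed(2)
  t_on <- sort(500 + cumsum(runif(300, 400, 600)))
  st <- stim_events(t_on, amplitude = 0.1)
  sp <- simulate_phase_population(cfg, max(t_on) + 500, stim = st,
                                  initial_phases = rep(0, cfg$n_osc))
  phi <- 0; t_prev <- 0; gen <- numeric(300)
  for (k in seq_len(300)) {
    phi <- phi + (t_on[k] - t_prev) / period
    gen[k] <- wrap_phase(phi)
    phi <- phi + 0.05 * sin(2 * pi * gen[k])
    t_prev <- t_on[k]
  }
  st$phase <- wrap_phase(gen + 0.25)
  rot <- estimate_prc(sp, st, n_bins = 16, pulses_per_burst = 1,
                      f0 = 1000 / period)
  shift <- c(5:16, 1:4)   # rotating origin by +0.25 moves samples 4 bins up
  expect_equal(rot$mean_advance[shift], prc$mean_advance,
               tolerance = 1e-8)
})

test_that("n_bins below 4 is rejected", {
  sp <- comb_record(make_comb(34, 2000))
  st <- stim_events(c(1000), amplitude = 0.1)
  expect_error(estimate_prc(sp, st, n_bins = 3), "at least 4")
})
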