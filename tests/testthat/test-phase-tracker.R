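# The time-weighted Fourier estimator: unit identities, linearity on pure
# combs, robustness on modulated-Poisson input, and trigger detection.

cfgT <- phase_tracker_config()

test_that("weighted Fourier coefficient obeys its defining identities", {
  t <- 1000
  # single spike exactly at t: weight exp(0) = 1
  x <- weighted_fourier(c(t), t, 34, cfgT)
  expect_equal(Mod(x), 1, tolerance = 1e-12, ignore_attr = TRUE)
  # spikes at t and t - tau: magnitudes 1 and exp(-1)
  x2 <- weighted_fourier(c(t - cfgT$tau, t), t, 0.0001, cfgT)
  expect_equal(Mod(x2), 1 + exp(-1), tolerance = 1e-6, ignore_attr = TRUE)
  # spikes outside the window contribute nothing
  x3 <- weighted_fourier(c(t - cfgT$window_T - 1, t), t, 34, cfgT)
  expect_equal(x3, weighted_fourier(c(t), t, 34, cfgT),
               tolerance = 1e-12, ignore_attr = TRUE)
  # empty window: zero coefficient, flagged
  x4 <- weighted_fourier(numeric(0), t, 34, cfgT)
  expect_identical(attr(x4, "n_window"), 0L)
  expect_equal(as.complex(x4), 0 + 0i, ignore_attr = TRUE)
})

test_that("phase of a pure comb advances linearly and shifts with the comb", {
  comb <- make_comb(34, 3000)
  ts <- seq(1000, 1000 + 2 * 1000 / 34, by = 0.5)
  phi <- vapply(ts, function(t) as.numeric(instantaneous_phase(comb, t, cfgT)),
                numeric(1))
  # unwrapped slope: one cycle per oscillation period (band centre 33 Hz
  # weighting pulls the slope slightly below 34; accept 2%)
  slope <- mean(wrap_signed(diff(phi))) / 0.5 * 1000
  expect_gt(slope, 31)
  expect_lt(slope, 35)
  # time-shift property: comb delayed by half a period -> phase shifted 0.5
  comb2 <- comb + 0.5 * 1000 / 34
  p1 <- as.numeric(instantaneous_phase(comb, 1500, cfgT))
  p2 <- as.numeric(instantaneous_phase(comb2, 1500, cfgT))
  expect_equal(wrap_phase(p1 - p2 + 0.25), 0.75, tolerance = 0.02)
  # wrap consistency: prepending whole periods changes nothing
  comb3 <- c(make_comb(34, 3000, t0 = -5 * 1000 / 34))
  p3 <- as.numeric(instantaneous_phase(comb3, 1500, cfgT))
  expect_equal(p1, p3, tolerance = 1e-9)
})

test_that("phase estimate is causal", {
  set.seed(42)
  s <- modulated_poisson(300, 34, t_end = 4000)
  t <- 2000
  full <- as.numeric(instantaneous_phase(s, t, cfgT))
  trunc <- as.numeric(instantaneous_phase(s[s <= t], t, cfgT))
  expect_identical(full, trunc)
})

test_that("incremental trace equals the direct estimator", {
  set.seed(7)
  s <- modulated_poisson(300, 34, t_end = 3000)
  tr <- phase_trace(s, cfgT, t_start = 1000, t_end = 1050)
  direct <- vapply(tr$t, function(t)
    as.numeric(instantaneous_phase(s, t, cfgT)), numeric(1))
  expect_equal(tr$phi, direct, tolerance = 1e-8)
})

test_that("estimator tracks the generative phase of modulated-Poisson input", {
  set.seed(1)
  phi0 <- 0.37
  s <- modulated_poisson(300, 34, t_end = 6000, phi0 = phi0)
  tr <- phase_trace(s, cfgT, t_start = 500, t_end = 5500)
  gen <- wrap_phase(34 * tr$t / 1000 - phi0)
  cc <- circ_corr(tr$phi, gen)
  expect_gt(cc, 0.9)
  # circular std of the error < 0.1 cycles
  err <- wrap_signed(tr$phi - gen)
  expect_lt(circ_sd(err), 0.1)
  # unwrapped slope within 2% of 34 cycles/s... of the band-weighted rate
  slope <- mean(wrap_signed(diff(tr$phi))) / cfgT$eval_dt * 1000
  expect_equal(slope, 34, tolerance = 0.02)
})

test_that("midpoint crossing detection interpolates and locks out", {
  # synthetic ramp: one crossing per 29.4 ms
  t <- seq(500, 800, by = 0.5)
  tr <- data.frame(t = t, phi = wrap_phase(t / 29.4), valid = TRUE,
                   n_spikes = 10L)
  class(tr) <- c("phase_trace", "data.frame")
  cr <- detect_midpoint_crossings(tr, nominal_period = 29.4)
  expect_true(all(abs(cr %% 29.4) < 0.05 | abs(cr %% 29.4 - 29.4) < 0.05))
  expect_equal(length(cr), floor(800 / 29.4) - floor(500 / 29.4))
  # constant phase: no crossings
  tr2 <- tr; tr2$phi <- 0.4
  expect_length(detect_midpoint_crossings(tr2), 0)
  # invalid evaluations never trigger
  tr3 <- tr; tr3$valid <- FALSE
  expect_length(detect_midpoint_crossings(tr3), 0)
})

test_that("inter-trigger intervals on a simulated parkinsonian run sit near one period", {
  cfg <- network_config("parkinsonian", seed = 3)
  sp <- simulate_network(cfg, 4000)
  tr <- phase_trace(sp, cfgT, t_start = 500)
  iti <- diff(detect_midpoint_crossings(tr))
  f0 <- estimate_f0(sp)
  expect_gt(length(iti), 50)
  expect_lt(abs(median(iti) - 1000 / f0) / (1000 / f0), 0.1)
})
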