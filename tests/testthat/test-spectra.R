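# Welch spectra of binned population rates and the band-ratio outcome.

poisson_record <- function(rate_hz = 2000, t_end = 6000, seed = 1) {
  set.seed(seed)
  n <- stats::rpois(1, rate_hz * t_end / 1000)
  comb_record(sort(stats::runif(n, 0, t_end)))
}

test_that("total spectral power matches the signal variance (Parseval)", {
  sp <- poisson_record()
  s <- population_spectrum(sp, t_start = 0)
  expect_equal(sum(s$power) * s$df, s$var_signal, tolerance = 0.01)
})

test_that("a homogeneous Poisson population has a flat spectrum", {
  ratios <- vapply(1:4, function(seed) {
    population_spectrum(poisson_record(seed = seed), t_start = 0)$beta_gamma_ratio
  }, numeric(1))
  expect_true(all(ratios > 0.5 & ratios < 2))
})

test_that("a 34 Hz modulated process peaks at 34 Hz", {
  set.seed(3)
  s <- modulated_poisson(2000, 34, t_end = 8000)
  spec <- population_spectrum(comb_record(s), t_start = 0)
  expect_equal(peak_frequency(spec), 34, tolerance = 1.01)
  expect_gt(spec$beta_gamma_ratio, 5)
})

test_that("fine frequency estimation resolves off-grid frequencies", {
  set.seed(4)
  f_true <- 34.4
  s <- modulated_poisson(3000, f_true, t_end = 20000)
  expect_equal(estimate_f0(comb_record(s), t_start = 0), f_true,
               tolerance = 0.1)
})

test_that("empty spike sets and too-short runs are rejected", {
  sp <- poisson_record(t_end = 6000)
  expect_error(population_spectrum(sp, t_start = 5500), "segment")
})

test_that("sham sweep outcome is zero against the identical off run", {
  off <- poisson_record(seed = 9)
  attr(off, "stim") <- stim_events(numeric(0))
  out <- phase_sweep_outcome(list(a = off), off, t_start = 0)
  expect_equal(out$pct_change, 0)
})
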