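# PRC-map and divergence predictions against analytic results and the
# two-oscillator brute-force oracle.

Zsin <- prc_function(sin_prc(0.05), harmonics = 4)

test_that("trigonometric smoothing reproduces a band-limited PRC exactly", {
  phi <- runif(50)
  expect_equal(prc_value(Zsin, phi), 0.05 * sin(2 * pi * phi), tolerance = 1e-10)
  expect_equal(prc_slope(Zsin, phi), 0.05 * 2 * pi * cos(2 * pi * phi),
               tolerance = 1e-8)
  # derivative integrates to zero over one period
  g <- (0:999) / 1000
  expect_lt(abs(mean(prc_slope(Zsin, g))), 1e-10)
})

test_that("PRC map: identity, rotation, and attraction to the stable fixed point", {
  Z0 <- prc_function(function(p) 0 * p)
  expect_equal(prc_map(Z0, c(0.1, 0.9)), c(0.1, 0.9))
  Zq <- prc_function(function(p) rep(0.25, length(p)))
  expect_equal(prc_map(Zq, 0.9), 0.15, tolerance = 1e-9)
  # iterate from 0.01: converges to phi = 0.5 where Z = 0, Z' < 0
  p <- 0.01
  for (i in 1:50) p <- prc_map(Zsin, p)
  expect_equal(as.numeric(p), 0.5, tolerance = 1e-3)
})

test_that("single-pulse pair separation matches the analytic slope", {
  expect_equal(pair_separation_single(Zsin, 0, eps = 1e-3),
               1e-3 * (1 + 0.1 * pi), tolerance = 1e-8)
  Zflat <- prc_function(function(p) rep(0.02, length(p)))
  expect_equal(pair_separation_single(Zflat, 0.3, eps = 2e-3), 2e-3,
               tolerance = 1e-9)
})

test_that("burst divergence reduces to the degenerate cases", {
  Z0 <- prc_function(function(p) 0 * p)
  expect_equal(divergence_burst(Z0, Z0, Z0, phi = c(0.1, 0.7), delta = 0.17,
                                eps = 1e-3), c(1e-3, 1e-3))
  # delta = 0 and null second/third pulses: equals the single-pulse formula
  expect_equal(divergence_burst(Zsin, Z0, Z0, phi = 0.2, delta = 0,
                                eps = 1e-3),
               pair_separation_single(Zsin, 0.2, 1e-3), tolerance = 1e-10)
})

test_that("burst divergence agrees with the two-oscillator brute-force oracle", {
  zfun <- function(p) 0.02 * sin(2 * pi * p)
  Z <- prc_function(zfun, harmonics = 2)
  phis <- (0:31) / 32
  delta <- 0.17
  pred <- divergence_burst(Z, phi = phis, delta = delta, eps = 1)
  brute <- vapply(phis, function(p)
    brute_burst_growth(zfun, p, delta, eps = 1e-3), numeric(1))
  expect_lt(max(abs(pred - brute) / abs(brute)), 0.05)
  # first-order error shrinks monotonically as eps decreases
  errs <- vapply(c(1e-2, 1e-3, 1e-4), function(eps) {
    b <- vapply(phis, function(p) brute_burst_growth(zfun, p, delta, eps),
                numeric(1))
    max(abs(pred - b))
  }, numeric(1))
  expect_true(all(diff(errs) < 0))
})

test_that("prediction curve: flat PRC gives unit growth; sinusoid optimum at max slope", {
  Zflat <- prc_function(function(p) rep(0.03, length(p)))
  pc <- prediction_curve(Zflat, pulses = 1, period_ms = 29.4)
  expect_true(all(abs(pc$growth - 1) < 1e-8))
  expect_true(all(abs(pc$minus_slope) < 1e-8))
  # one small pulse: sign of prediction equals sign of -Z' everywhere
  pc2 <- prediction_curve(Zsin, pulses = 1, period_ms = 29.4)
  big <- abs(pc2$minus_slope) > 1e-9
  expect_true(all(sign(pc2$growth[big] - 1) == sign(-pc2$minus_slope[big])))
  # optimal single-pulse phase = argmax Z' (phi = 0 for a sine PRC)
  opt <- optimize_stimulus(Zsin, pulses = 1)
  expect_lt(min(abs(c(opt$phase, opt$phase - 1))), 0.01)
})

test_that("grid-search optimum survives a 10x finer refinement", {
  opt <- optimize_stimulus(Zsin, pulses = 3, period_ms = 29.4,
                           delta_bounds_ms = c(1, 10), n_phase = 64,
                           n_delta = 10)
  fine <- optimize_stimulus(Zsin, pulses = 3, period_ms = 29.4,
                            delta_bounds_ms = c(1, 10), n_phase = 640,
                            n_delta = 100)
  expect_lt(abs(fine$growth - opt$growth) / fine$growth, 0.05)
  dphi <- min(abs(c(fine$phase - opt$phase, fine$phase - opt$phase + 1,
                    fine$phase - opt$phase - 1)))
  expect_lt(dphi, 1 / 64 + 1e-9)
})

test_that("a burst outgrows a single pulse when the positive-slope region is wide", {
  # skewed PRC: long shallow rise over ~60% of the cycle, sharp fall
  zfun <- function(p) 0.03 * (sin(2 * pi * p) + 0.45 * sin(4 * pi * p + 0.6))
  Z <- prc_function(zfun, harmonics = 3)
  g1 <- max(prediction_curve(Z, pulses = 1, period_ms = 29.4)$growth)
  g3 <- max(prediction_curve(Z, pulses = 3, delta_ms = 5,
                             period_ms = 29.4)$growth)
  expect_gte(g3, g1)
})

test_that("composed burst PRC linearly sums per-pulse advances", {
  delta <- 5 / 29.4
  Zb <- compose_burst_prc(Zsin, pulses = 3, delta = delta)
  phi <- (0:63) / 64
  direct <- vapply(phi, function(p) {
    cum <- 0
    for (k in 0:2) cum <- cum + 0.05 * sin(2 * pi * (p + cum + k * delta))
    cum
  }, numeric(1))
  expect_equal(prc_value(Zb, phi), direct, tolerance = 2e-3)
})
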