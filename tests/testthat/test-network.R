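# The spiking-network surrogate: determinism, regime separation, the
# subthreshold stimulation contract, input validation.

test_that("a fixed seed reproduces spikes bitwise", {
  cfg <- network_config("parkinsonian", seed = 17)
  a <- simulate_network(cfg, 1500)
  b <- simulate_network(cfg, 1500)
  expect_identical(a$t, b$t)
  expect_identical(a$neuron, b$neuron)
  expect_identical(as.character(a$population), as.character(b$population))
})

test_that("beta power separates the parkinsonian from the healthy regime", {
  betas <- sapply(1:3, function(s) {
    pd <- population_spectrum(
      simulate_network(network_config("parkinsonian", seed = s), 3000),
      t_start = 500)$beta_power
    hl <- population_spectrum(
      simulate_network(network_config("healthy", seed = s), 3000),
      t_start = 500)$beta_power
    c(pd = pd, hl = hl)
  })
  expect_true(all(betas["pd", ] > betas["hl", ]))
})

test_that("a default-amplitude pulse cannot fire a quiescent STN neuron", {
  cfg <- network_config("parkinsonian", seed = 1,
                        neuron = list(bias_mean = c(4, 0, 0),
                                      bias_sd = c(0, 0, 0)),
                        cortical_drive = list(rate_burst = 0, rate_base = 0),
                        striatal_drive = list(rate_gpe = 0, rate_gpi = 0),
                        background = list(rate = 0))
  st <- stim_events(200, amplitude = 0.1)
  sp <- simulate_network(cfg, 400, stim = st)
  expect_length(spike_times(sp, "STN"), 0)
})

test_that("invalid durations and stimulus times are rejected", {
  cfg <- network_config("parkinsonian")
  expect_error(simulate_network(cfg, 10), "cycle")
  expect_error(simulate_network(cfg, 1000, stim_events(2000, amplitude = 0.1)),
               "within")
})

test_that("full-amplitude 136 Hz open-loop stimulation suppresses beta", {
  cfg <- network_config("parkinsonian", seed = 2)
  off <- simulate_network(cfg, 8000)
  proto <- protocol_config("openloop", amplitude = 1, volley = TRUE)
  on <- run_protocol(cfg, 8000, proto, tracker = NULL)
  b_off <- population_spectrum(off)$beta_power
  b_on <- population_spectrum(on)$beta_power
  expect_lt(b_on, b_off)
})

test_that("the cortical drive leaves a 16 Hz signature in the healthy state", {
  hl <- simulate_network(network_config("healthy", seed = 1), 5000)
  spec <- population_spectrum(hl)
  expect_equal(peak_frequency(spec, c(10, 25)), 16, tolerance = 1.01)
})
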