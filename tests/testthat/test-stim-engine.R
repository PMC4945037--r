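# Protocol generation: burst arithmetic, truncation, open-loop trains,
# energy accounting.

test_that("closed-loop burst arithmetic matches the protocol", {
  proto <- protocol_config("phabs", isi_delta = 5, amplitude = 0.1)
  st <- schedule_closed_loop(100, proto, delay = 8.8)
  expect_equal(st$t_on, c(108.8, 113.8, 118.8))
  expect_equal(unique(st$burst), 1L)
  single <- protocol_config("phasic_single")
  expect_equal(schedule_closed_loop(100, single, delay = 0)$t_on, 100)
  expect_error(schedule_closed_loop(100, single, delay = -1), "non-negative")
})

test_that("a 3-pulse burst at 5 ms spacing covers about 30% of a 34 Hz period", {
  proto <- protocol_config("phabs", isi_delta = 5)
  st <- schedule_closed_loop(0, proto, delay = 0)
  span <- max(st$t_on) - min(st$t_on)          # 10 ms
  expect_equal(span / (1000 / 34), 0.34, tolerance = 0.15)
})

test_that("bursts are truncated at the next trigger", {
  proto <- protocol_config("phabs", isi_delta = 5)
  st <- schedule_closed_loop(c(100, 111), proto, delay = 4)
  # burst 1 pulses at 104, 109 (114 dropped: after trigger 2 at 111)
  expect_equal(st$t_on[st$burst == 1], c(104, 109))
  expect_equal(st$t_on[st$burst == 2], c(115, 120, 125))
})

test_that("open-loop trains are uniform at the configured rate", {
  proto <- protocol_config("openloop", openloop_rate = 136, amplitude = 1)
  st <- schedule_open_loop(proto, 1000)
  expect_equal(nrow(st), 136)
  expect_equal(unique(round(diff(st$t_on), 3)), 7.353)
  probe <- protocol_config("probe", probe_rate = 2, burst_pulses = 1)
  st2 <- schedule_open_loop(probe, 100e3)
  expect_equal(nrow(st2), 200)
})

test_that("2 Hz probes cover the phase axis of the emergent cycle uniformly", {
  # the emergent period is 29.4 ms (34.01 Hz), not exactly 17 cycles per
  # probe, so successive probes precess slowly around the circle
  probe <- protocol_config("probe", probe_rate = 2, burst_pulses = 1)
  st <- schedule_open_loop(probe, 400e3)
  ph <- wrap_phase(st$t_on / 29.4)
  h <- table(cut(ph, seq(0, 1, by = 0.125), include.lowest = TRUE))
  expect_gt(stats::chisq.test(h)$p.value, 0.01)
})

test_that("every scheduled pulse is causal and charge is accounted", {
  proto <- protocol_config("phabs", amplitude = 0.1, width = 0.5)
  trig <- cumsum(rep(29.4, 20))
  st <- schedule_closed_loop(trig, proto, delay = 3)
  expect_true(all(st$t_on >= rep(trig, table(st$burst))))
  expect_equal(delivered_charge(st), nrow(st) * 0.1 * 0.5)
  # phase-locked bursts at 0.1 amplitude use less charge per second than
  # open-loop 136 Hz at reference amplitude
  phabs_charge <- delivered_charge(st) / (max(trig) / 1000)
  ol <- schedule_open_loop(protocol_config("openloop", amplitude = 1), 1000)
  expect_lt(phabs_charge, delivered_charge(ol) / 1)
})
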