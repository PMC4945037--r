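# Canonical configuration of the subthalamopallidal surrogate network.
# The base section is the healthy regime; the `parkinsonian` section lists
# the complete set of overrides that define the parkinsonian regime
# (stronger STN<->GPe coupling plus increased striatal inhibition of GPe).
# All tuned values below are the repository's canonical parameter set.
network:
  n_stn: 100
  n_gpe: 300
  n_gpi: 100
  dt: 0.05            # ms, fixed-step Euler
  seed: 1
  neuron:
    E_leak: -65.0     # mV
    E_exc: 0.0
    E_inh: -80.0
    V_thresh: -50.0
    V_reset: -60.0
    t_ref: 2.0        # ms
    tau_exc: 2.0      # ms, excitatory conductance decay
    tau_inh: 3.5      # ms, inhibitory conductance decay
    tau_m: [12.0, 10.0, 10.0]       # ms: STN, GPe, GPi
    bias_mean: [22.0, 12.0, 17.0]   # mV tonic drive: STN, GPe, GPi
    bias_sd: [2.0, 2.0, 2.0]
  coupling:
    stn_gpe: {K: 15, w: 0.015, delay: 2.7}   # excitatory
    gpe_stn: {K: 15, w: 0.020, delay: 2.7}   # inhibitory
    stn_gpi: {K: 15, w: 0.030, delay: 3.0}   # excitatory
    gpe_gpi: {K: 15, w: 0.040, delay: 3.0}   # inhibitory
    gpe_gpe: {K: 10, w: 0.015, delay: 1.0}   # inhibitory collaterals
  cortical_drive:      # 16 Hz stochastic bursting input to STN
    rate_hz: 16.0
    burst_frac: 0.3    # fraction of each cycle occupied by the burst
    rate_burst: 400.0  # Hz per neuron during the burst
    rate_base: 40.0    # Hz per neuron between bursts
    gain_sd: 0.4       # lognormal sigma of the per-cycle gain
    w: 0.040
  striatal_drive:      # Poisson inhibitory drive
    rate_gpe: 200.0    # Hz per GPe neuron
    rate_gpi: 200.0
    w: 0.02
  background:          # unstructured excitatory noise to all populations
    rate: 550.0        # Hz per neuron
    w: 0.010
  stim:
    ref_amp: 60.0      # mV drive at amplitude = 1: the reference amplitude,
                       # calibrated as the smallest drive for which a majority
                       # of STN spikes lock within 2 ms of 136 Hz pulses
    width: 0.5         # ms
    w_volley: 0.15     # efferent synaptic volley per unit amplitude
    volley_delay: 1.0  # ms
  parkinsonian:        # overrides applied on top of the base (healthy) state
    coupling:
      stn_gpe: {w: 0.300}
      gpe_stn: {w: 0.250}
    striatal_drive:
      rate_gpe: 600.0

tracker:
  window_T: 400.0      # ms
  tau: 3.0             # ms
  f_min: 30.0          # Hz
  f_max: 36.0
  f_step: 1.0
  eval_dt: 0.5         # ms

protocol:
  openloop_rate: 136.0 # Hz
  probe_rate: 2.0      # Hz
  n_delays: 10
  burst_pulses: 3
  isi_delta: 5.0       # ms
  amplitude: 0.1       # fraction of reference amplitude
  width: 0.5           # ms
  duration: 100.0      # s

prc:
  n_bins: 16
  window_len: 94.0     # ms
  guard: 0.0
  harmonics: 4

spectra:
  beta_band: [31.0, 36.0]
  gamma_band: [60.0, 64.0]
  bin_ms: 1.0
  segment_s: 1.0
  overlap: 0.5
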