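---
title: "Phasic burst stimulation: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phasic burst stimulation: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6,
                      fig.height = 4, eval = FALSE)
```

`phabs` implements a closed-loop neuromodulation design pipeline: estimate
the instantaneous phase of a pathological population oscillation from spike
times alone, measure the population's phase response curve (PRC), and use
the PRC's slope to choose when — and with how many pulses — to stimulate in
order to desynchronize the oscillation.  This vignette explains the science
inside each module, the tunable parameters, and the choices made where the
design was genuinely open.

## The population oscillation and its surrogate network

The testbed is a spiking surrogate of the subthalamopallidal circuit: 100
excitatory subthalamic (STN) neurons, 300 inhibitory external-pallidal (GPe)
neurons and 100 inhibitory internal-pallidal (GPi) readout neurons, as
single-compartment leaky integrate-and-fire units with conductance synapses,
sparse random connectivity with conduction delays, Poisson background noise,
a 16 Hz stochastically bursting cortical drive to STN, and Poisson striatal
inhibition of GPe/GPi.  All parameters live in one YAML file
(`default_config.yaml`); the *parkinsonian* regime differs from the
*healthy* one only through a three-entry override table: stronger STN→GPe
and GPe→STN coupling and tripled striatal drive to GPe.

In the parkinsonian regime the delayed excitatory–inhibitory loop between
STN and GPe resonates and an emergent ~34 Hz rhythm appears in the GPe
population rate, with GPe discharging in tight once-per-cycle packets; in
the healthy regime the loop gain is too low and only the 16 Hz cortical
signature remains.  The rhythm is an emergent property of the coupled loop —
no neuron is an intrinsic 34 Hz oscillator.  The oscillation frequency is
set mainly by the loop delay (2 × 2.7 ms conduction plus synaptic and
membrane lags); the packet sharpness by the coupling strength and the
background noise rate.

Two quenched/annealed randomness streams are kept separate on purpose:
`structure_seed` freezes the network *instance* (connectivity, per-neuron
biases, initial conditions) and `seed` varies only the input noise.
Repeated runs with different `seed`s therefore probe the same "subject",
the way repeated stimulation sessions in one patient would; confidence
intervals in the phase sweeps are computed across such noise realizations.
This matters because the phase origin of the online estimator is a property
of the network instance: averaging delay-keyed outcomes across different
instances would scramble the phase axis.

The stimulus is a rectangular current pulse (default width 0.5 ms) injected
into every STN neuron.  Amplitudes are expressed as fractions of a
*reference amplitude*, calibrated (see
`calibrate_reference_amplitude()`) as the smallest amplitude that entrains
STN firing to a 136 Hz open-loop train; closed-loop protocols default to
0.1 × reference, small enough that a pulse cannot fire a quiescent STN
neuron — it only shifts the phase of ongoing activity.  At full reference
amplitude an optional synaptic volley to GPe/GPi models activation of STN
efferents by clinical-intensity stimulation.

## Online phase estimation from spike times

The tracker computes a time-weighted Fourier coefficient of the GPe spike
times $S_k$ in the trailing $T = 400$ ms,

$$X(f,t) = \sum_k e^{(S_k - t)/\tau}\, e^{-2\pi i f S_k},\qquad \tau = 3\ \mathrm{ms},$$

and reads the instantaneous phase (in cycles) from the angle of
$\sum_{f=30}^{36} X(f,t)\, e^{2\pi i t f}$ on a 1 Hz frequency grid.  The
closed-loop controller evaluates this every 0.5 ms, triggers when the phase
wraps through zero (with linear sub-grid interpolation), and enforces a
half-period lockout against estimator jitter.

Two properties of this estimator shape everything downstream:

* **Effective memory.** With $\tau \ll T$ the weights decay e-fold every
  3 ms, so although the window is 400 ms long the estimate is dominated by
  the last few cycles.  The package implements the definition exactly as
  stated (the window and $\tau$ are both configurable) rather than
  reinterpreting $\tau$.
* **The tonic-firing offset.** Splitting the population rate into a tonic
  part $\lambda_0$ and a modulated part of fundamental amplitude
  $\lambda_1$, the tonic part contributes a *constant* complex offset to the
  phase sum while only the modulated part rotates.  With $\tau = 3$ ms the
  rotating part outweighs the offset only when
  $\lambda_1/\lambda_0 \gtrsim 1.7$ — i.e. when the population fires in
  sharp per-cycle packets.  A sinusoidally modulated rate can never reach
  this ($\lambda_1/\lambda_0 \le 1$), so the estimator's robustness tests
  use packet-like (von Mises, $\kappa = 8$) rate modulation, which is also
  what the parkinsonian GPe discharge looks like.  One visible consequence
  remains: the estimated phase advances non-uniformly within a cycle, so
  probe phases concentrate at low values and PRC experiments need more
  probes (the package's experiments use 600-1000 rather than 200) to fill the tail bins.

## Measuring the population PRC

Probes are delivered open-loop at 2 Hz (single pulses for the first-order
PRC; bursts of three, 5 ms apart, for the burst PRC).  Each probe
contributes one sample: its *phase* is the online estimate at first-pulse
onset, and its *advance* is the angular difference between Fourier
coefficients at the oscillation frequency $f_0$ fitted to 94 ms windows
ending at pulse onset and starting at burst offset, mapped to
$(-0.5, 0.5]$ cycles with positive = advance.  Because both windows are
referenced to absolute time, an unperturbed oscillation at exactly $f_0$
yields zero — but a frequency mismatch of $\Delta f$ biases every advance by
$\Delta f \times 94\ \mathrm{ms}$ cycles.  $f_0$ is therefore estimated
from a full-length periodogram with quadratic peak interpolation
(`estimate_f0()`), not from the 1 Hz Welch grid.

Per-bin statistics use the wrapped-normal fit: circular mean and dispersion
$\sqrt{-2\log R}$ of the resultant length $R$.  Invalid phases and empty
windows exclude the probe and are counted in an exclusion log.  Sixteen
bins are the default; smoothing for differentiation uses weighted
trigonometric least squares with at most four harmonics — finite
differences on noisy binned means are unusable, and a low harmonic cap is
the mildest periodic smoother with an analytic, zero-mean derivative.

## Predictions: maps, slopes and bursts

For once-per-cycle stimulation the PRC defines the map
$\phi_{i+1} = \phi_i + Z(\phi_i)$, and two nearby oscillators separate as
$\epsilon_{i+1} = \epsilon_i (1 + Z'(\phi_i))$: phases with positive PRC
slope desynchronize.  For a burst of $n$ pulses separated by $\delta$
cycles the package composes per-pulse factors

$$\epsilon_{i+1} = \epsilon_i \prod_{k=1}^{n} \bigl(1 + Z_k'(a_k)\bigr),
\qquad a_k = \phi_i + \sum_{j<k} Z_j(a_j) + (k-1)\delta,$$

evaluated literally: the inter-pulse drift accumulates linearly and each
pulse adds its own resetting.  `divergence_burst()` exposes the
three-pulse case and the general recursion; `prediction_curve()` returns
the per-phase growth together with $-Z'(\phi)$ (negative values mark
desynchronizing phases); `optimize_stimulus()` grid-searches (phase,
$\delta$), breaking ties toward the smallest $\delta$.  Growth is reported
as $|\epsilon_{i+1}/\epsilon_i|$; factors below $-1$ (overcorrection) are
flagged, not clipped.  The per-pulse PRCs $Z_1, Z_2, Z_3$ default to a
common $Z$; a directly measured burst PRC that deviates from the composed
first-order prediction is the package's detector for higher-order
resetting.

These predictions are verified against a brute-force oracle: two phase
oscillators at separation $\epsilon$, kicked and drifted explicitly.  The
relative error of the product formula decreases as $\epsilon \to 0$
(checked at $10^{-2}, 10^{-3}, 10^{-4}$) and is below 5% at
$\epsilon = 10^{-3}$.

## The phase-oscillator backend

`simulate_phase_population()` runs $n$ phase oscillators with a known
generative PRC, per-cycle Gaussian jitter and spike emission at each wrap,
returning spikes in the same form as the network so every downstream module
is backend-agnostic.  It is *memoryless by construction*: each pulse's
effect depends only on the phase at which it lands, so a measured burst PRC
must match the composed first-order prediction — the contrast with the
network (where they differ) is what demonstrates higher-order effects.
Kicks scale linearly with amplitude relative to a reference (`amp_ref`),
which gives the linearity-in-amplitude property its oracle.  Each
oscillator owns an independent RNG stream, so stimulation cannot reorder
jitter draws — a null (zero) PRC provably leaves spike trains unchanged.

## Outcome measure and experiments

The outcome of every stimulation run is the ratio of beta (31–36 Hz) to
gamma (60–64 Hz) band power of the 1 ms-binned GPe population rate,
computed by a Welch average (1 s rectangular segments, 50% overlap, each
segment demeaned), expressed as percent change from the stimulation-off run
of the same seed.  The gamma band serves as a stimulation-insensitive
reference.  The tracker's 30–36 Hz band and the outcome's 31–36 Hz band
are deliberately kept as separately configurable quantities.  One caveat:
for a *near-coherent* oscillator population (the phase backend under
entraining stimulation) the rhythm's second harmonic (~68 Hz) leaks into
the gamma band and invalidates the reference; `phase_sweep_outcome()`
therefore offers `outcome = "beta"` (raw beta power), which the
phase-backend tests use.  The spiking network's broader packets and higher
gamma-band noise floor keep the ratio outcome valid there.

`run_phase_sweep()` sweeps 10 trigger-to-pulse delays spanning one nominal
period, with one closed-loop run per delay per noise seed and matched off
runs; `run_prc_experiment()` measures the single-pulse or burst PRC; and
`compare_prediction_to_sweep()` scores per-delay sign agreement between
predicted growth and measured suppression plus a Spearman rank correlation.

Desk-scale problem sizes used throughout the shipped tests and the
acceptance script: 10 s baselines for spectra, 20 s per delay and three
noise seeds for sweeps (off runs shared between protocols), and several
hundred 2 Hz probes for PRCs.  The
`scale` field of an `experiment_spec()` shrinks durations and populations
together for quick exploration.

## What the surrogate does and does not show

The network reproduces the phenomenology the method needs — an emergent
beta-band rhythm present only in the parkinsonian regime, suppressed by
high-frequency open-loop stimulation, phase-dependently modulated by
subthreshold phase-locked pulses (suppression when stimulating early in
the estimated cycle, enhancement late), and a measurable population PRC
with a contiguous positive-slope region.  It is not a biophysical
reconstruction: neurons are integrate-and-fire rather than multi-channel
conductance models, wiring is random rather than topographic, healthy-state
firing rates are not fit to primate recordings, and STN tonic rates in the
healthy regime run high because the tonic bias that sustains the
parkinsonian loop is shared between regimes.  Passing tests therefore
certify the *method* — estimator, PRC measurement, predictions, closed
loop — on a system with the right qualitative physiology, not a
patient-level forecast.

Known numerical choices and edge cases, in one place: fixed-step Euler at
`dt = 0.05` ms with synaptic delays rounded to steps and pulse onsets
quantized to the evaluation grid; the closed loop consumes only
already-emitted spikes (one-chunk latency, strict causality); bursts still
pending at the next trigger are truncated; phase values with an empty
tracker window are flagged invalid and can never trigger; empty advance
windows exclude a probe; zero-count PRC bins are flagged and excluded from
smoothing; and all public phases are in cycles, radians appearing only
inside the estimators.
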