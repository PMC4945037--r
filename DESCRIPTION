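Package: phabs
Title: Phase Response Curve Guided Closed-Loop Burst Stimulation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Design and in-silico testing of phasic burst stimulation (PhaBS),
    a closed-loop deep-brain-stimulation protocol that locks short bursts of
    subthreshold pulses to the phase of an ongoing pathological population
    oscillation.  Provides online phase estimation from spike trains via a
    time-weighted Fourier transform, estimation of population phase response
    curves (PRCs) with wrapped-normal statistics, PRC-map and multi-pulse
    divergence predictions of desynchronizing stimulus phases, band-power
    outcome measures, and a tuned spiking-network surrogate of the
    subthalamopallidal circuit (STN/GPe/GPi) whose parkinsonian regime
    exhibits an emergent beta-band oscillation, together with an analytic
    phase-oscillator population backend used as an oracle.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
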