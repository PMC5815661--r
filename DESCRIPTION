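Package: rpaccum
Title: Leaky Stochastic Accumulator Modelling of the Readiness Potential
    with Temporally Autocorrelated Input Noise
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulates a leaky stochastic accumulator driven by 1/f
    ("pink") input noise and uses it to model the readiness potential
    (RP) preceding self-initiated movement. Provides FFT-based spectral
    shaping of Gaussian noise to an arbitrary 1/f exponent, first-passage
    simulation with a two-threshold account of the subjectively reported
    time of the urge to move ('W' time), IRASA-based estimation of the
    aperiodic spectral exponent, simultaneous Nelder-Mead fitting of an
    event-locked waveform and a waiting-time distribution, tercile-split
    waveform comparisons with cluster-based permutation correction,
    waiting-time/W-time correlation analyses, and a generator of
    synthetic multi-subject cohorts with the data structure the analyses
    assume.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
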