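Package: ovclamp
Title: Closed-Loop Optogenetic Voltage Clamp: Simulation, Control and Trace Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A digital twin of an all-optical voltage clamp for excitable cells.
    Simulates a single-compartment membrane driven by two spectrally opposed
    photocurrents (a red-shifted depolarizer and a blue-shifted hyperpolarizer)
    and a linear fluorescent voltage sensor with photobleaching and shot noise.
    Provides the closed-loop feedback laws used to hold relative fluorescence
    (dF/F0) at a setpoint by steering the actuation wavelength: a decision-tree
    integral controller with tolerance band and wavelength limits, a discrete
    PID controller with Ziegler-Nichols tuning, and a scalar Kalman filter for
    sensor smoothing. Includes live exponential bleach correction, step,
    pseudo-I/V, optical current clamp and on-the-run protocols with a text
    results file, and offline analysis: calibration regressions with
    heteroscedasticity-consistent standard errors and the White test,
    fluorescence-to-voltage and wavelength-to-current conversion, transition
    times and control-quality metrics, and action-potential detection
    (amplitude, FWHM, rise time constant).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    minpack.lm,
    sandwich,
    yaml
Suggests:
    testthat (>= 3.0.0),
    lmtest,
    jsonlite,
    optparse
Config/testthat/edition: 3
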