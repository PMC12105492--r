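Package: sapwave
Title: Biosensor Calibration, Xylem Transport Modelling, and Kinetics of
    Systemic H2O2 and Variation-Potential Waves in Plants
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing stem-implanted fiber organic electrochemical
    transistor (fOECT) recordings of plant systemic signalling. Fits log-linear
    sensor calibration curves and signal-to-noise detection limits; models
    transpiration-driven solute transport along the stem with a 1D convection
    model (plus a diffusion null model) and estimates the xylem flow rate by
    least squares; extracts wave kinetics (take-off, delay, amplitude, rise
    time, propagation velocity, exponential distance decay, rise-time floors)
    from hydrogen peroxide and variation-potential traces; simulates a
    mechanistic 1D cell lattice in which H2O2 production and membrane
    depolarization mutually reinforce a propagating wave, with xylem advection,
    plasmodesmal calcium exchange, and pharmacological blockade zones; and
    generates phenomenological synthetic datasets for end-to-end parameter
    recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    minpack.lm,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
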