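Package: tfoptics
Title: Transabdominal Fetal Oximetry by Diffuse Optics: Simulation, Signal Extraction and Estimation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying non-invasive fetal arterial oxygen saturation
    (fSpO2) sensing through the maternal abdomen with continuous-wave near
    infrared light. Provides a white (absorption-free) Monte Carlo simulator of
    photon transport in a four-layer pregnant-abdomen model recording per-layer
    partial pathlengths, a forward engine for normalized intensity, fetal
    sensitivity, the Exponential Pulsation Ratio (EPR) and the conventional
    Ratio-of-Ratios (RoR), physiologically motivated photodetector noise
    injection, a synthetic frequency-multiplexed dual-wavelength
    photoplethysmography pipeline (demodulation, lower envelope, lock-in
    detection, EPR extraction), and a multi-layer-perceptron fusion estimator
    of fSpO2 from multi-detector EPR features with random and temporal
    validation schemes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    signal,
    zoo,
    stats,
    utils,
    yaml,
    jsonlite,
    generics
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
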