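Package: pulseoxmc
Title: Monte Carlo Modelling of Skin-Pigmentation Bias in Transmittance Pulse Oximetry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Layered-tissue Monte Carlo photon transport through a model human
    finger for transmittance pulse oximetry. Builds wavelength-resolved optical
    properties for skin, fat, muscle and bone from chromophore composition
    (melanin, hemoglobin, water), simulates systolic and diastolic
    transmittance at 660 and 940 nm with a weighted hop-drop-spin engine,
    derives AC/DC perfusion indices and the ratio of ratios, fits SpO2
    calibration curves per skin phototype, quantifies calibration bias against
    a commercial relation, and computes skin-tone correction multipliers.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
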