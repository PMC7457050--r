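Package: mosstherm
Title: Photosynthetic Temperature Responses and Carbon Balance of Antarctic Mosses
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Analysis pipeline for moss ecophysiology: summarises canopy-surface
    temperature logger traces into frequency-of-time histograms, computes
    pulse-modulated chlorophyll fluorescence parameters (phiPSII, NPQ, Fv/Fm)
    and electron transport rates, fits rapid light-response curves (rational
    and waiting-in-line models) to extract AQE and ETRmax, fits cubic
    temperature-response curves and extracts optimum temperatures and Q10
    coefficients, estimates mesophyll conductance by the variable-J
    (Harley-type) method adapted for astomatous bryophytes with alpha-beta and
    light-respiration calibration from low-O2 light curves, partitions
    mesophyll versus biochemical limitations, and combines microclimate
    histograms with assimilation temperature responses into carbon-balance
    scenarios under partial inhibition of sub-threshold respiration. A
    synthetic-data module generates all inputs with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    minpack.lm,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
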