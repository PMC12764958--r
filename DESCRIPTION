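Package: porhmeso
Title: Skin Microvascular Endothelial Function from Optoacoustic Mesoscopy
    PORH Time Series
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis of cutaneous post-occlusive reactive
    hyperemia (PORH) measured by raster-scan optoacoustic mesoscopy (RSOM).
    Provides a forward model for broadband optoacoustic raw scans of skin
    vascular phantoms, dual-band delay-and-sum beamforming reconstruction,
    skin surface flattening and epidermis/dermis layer segmentation, and
    layer-resolved endothelial-function biomarkers (maximum volume change,
    hyperemia ratio, time-to-peak) with vessel-diameter (FWHM), blood-volume
    and depth-resolved time-to-peak metrics. The central fit, porh_fit(),
    returns a classed model object with the usual methods. Synthetic cohort
    generators with known ground truth support parameter-recovery testing and
    group statistics (normality-gated parametric/nonparametric comparisons,
    repeatability metrics).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    signal,
    jsonlite,
    yaml,
    tiff,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
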