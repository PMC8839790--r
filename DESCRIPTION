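Package: aquaheat
Title: Aquaphotomics Analysis of Heat-Treated Unifloral Honeys
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A chemometric pipeline for detecting heat treatment of honey
    from near-infrared water absorbance spectra. Provides a spectra data
    model with replicate/fill/scan metadata, PCA-based outlier screening,
    spectral pretreatment operators (Savitzky-Golay, SNV, MSC, detrending)
    with a 41-combination optimization grid, PCA, hybrid PCA-LDA
    classification and PLS regression with replicate-blocked
    cross-validation, subtraction spectra, wavelength voting into the 12
    water matrix coordinates (WAMACs), classic aquagram computation and
    radar rendering, ANOVA and Tukey/Games-Howell post hoc statistics for
    hydroxymethylfurfural (HMF) content (raw or summary-statistics mode),
    and a synthetic spectra generator emulating the three-honey heat
    treatment study design so the whole pipeline is testable end to end.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    car
Suggests:
    testthat (>= 3.0.0),
    MASS,
    withr,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
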