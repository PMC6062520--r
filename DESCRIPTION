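Package: wcmaldi
Title: Whole-Cell MALDI-TOF Drug-Response Marker Discovery
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Automated analysis of lipid and metabolite drug-response markers
    from whole-cell MALDI-TOF mass spectrometry fingerprints. Provides spectrum
    preprocessing (TIC normalization, Top-Hat baseline subtraction, peak picking,
    relative-tolerance peak binning into a feature matrix), multivariate
    fingerprint scores (PCA, cluster-separation and matrix-suppression scores),
    variance-based feature filtration, four-parameter logistic
    concentration-response fitting with biphasic truncation and pIC50
    extraction, accurate-mass compound annotation (adduct arithmetic with
    electron-mass correction, ppm matching, isotope patterns, neutral-loss
    fragment assignment), and a synthetic-spectrum simulator for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    jsonlite
Suggests:
    mzR,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
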