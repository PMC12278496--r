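Package: optirpop
Title: Single-Cell O-PTIR Spectroscopy Analysis of Population Heterogeneity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis pipeline for single-cell optical photothermal infrared
    (O-PTIR) microspectroscopy of oleaginous yeast populations. Provides a
    forward simulator of single-point O-PTIR spectra and segmentation masks,
    Savitzky-Golay second-derivative preprocessing with region truncation and
    vector normalization, Pearson-distance (1-PCC) intra- and inter-cell
    variability statistics with IQR outlier flagging, principal component
    analysis of fingerprint-region spectra, size-stratified carbonyl band-ratio
    chemistry for triacylglycerol, free fatty acid and protein content, and a
    simulation of sparse four-wavenumber acquisition.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    png,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
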