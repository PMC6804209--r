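Package: lsrm
Title: Line-Scan Raman Microspectroscopy Analysis of Pituitary Tissue
Version: 0.1.0
Authors@R:
    person("LSRM", "Maintainers", email = "lsrm-maintainers@example.org",
           role = c("aut", "cre"))
Description: Label-free Raman diagnostic analysis for pituitary tissue:
    spectral preprocessing (transmission correction, iterative polynomial
    autofluorescence removal, Savitzky-Golay smoothing, region cropping,
    0-1 normalization), PCA plus k-nearest-neighbor classification of
    tissue classes, hyperspectral band-image visualization, grey-level
    co-occurrence matrix (Haralick) texture quantification, and
    inter-class image correlation.  Includes a synthetic-spectrum and
    hyperspectral-cube generator emulating pituitary gland, five adenoma
    subtypes and periosteal layer, so the full pipeline is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Imports:
    grDevices,
    graphics,
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
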