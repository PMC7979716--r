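Package: ngiplex
Title: Virtual Multiplexed Immunohistochemistry and Spatial Immune
    Contexture Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for sequential ("next-generation") chromogenic
    immunohistochemistry: Beer-Lambert optical-density conversion and
    two-stain colour deconvolution, rigid registration of repeated
    staining rounds into a virtual multiplexed image, watershed nucleus
    detection with compartment-restricted marker calling and exclusive
    T-cell phenotyping, cytokeratin-based tumour masking with
    distance-band stromal zoning, per-sample immune-contexture metrics
    (densities, Ki67 co-expression, subset proportions), and the
    accompanying statistics layer (exact rank tests, paired-difference
    intervals, logistic odds ratios, housekeeping normalisation and
    quantitative SAM for gene-TIL association). Includes a seeded
    synthetic slide and cohort generator with full ground truth so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    stats,
    utils,
    tiff,
    png,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
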