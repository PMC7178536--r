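Package: qams
Title: Single-Marker Multicomponent Quantification and Quality Grading for
    HPLC Chromone Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of multicomponents by single marker (QAMS)
    for HPLC assays of the six bioactive chromones of Saposhnikoviae Radix,
    with the conventional external standard method (ESM) alongside for
    comparison. Fits linear calibration curves with LOD/LOQ from
    signal-to-noise, computes relative correction factors and their
    durability across instruments and conditions, assigns chromatographic
    peaks by relative retention time, converts peak areas to mass fractions,
    and grades herbal batches by correlation-matrix PCA composite scores and
    hierarchical clustering of totals and aglycone ratios. Includes a
    synthetic-data generator emulating detector response, retention-time
    jitter and between-batch content variation, and packaged reference
    tables for the published 55-batch dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
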