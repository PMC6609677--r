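Package: rbflow
Title: Tumor Blood Flow Quantification and Test-Retest Repeatability for Rb-82 PET
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Quantifies tumor blood flow from dynamic and static Rb-82 PET and
    analyses its test-retest repeatability. Implements one-tissue-compartment
    kinetic modelling with a cluster-derived, delay- and dispersion-corrected
    image-derived input function, SUV metrics on threshold-segmented volumes
    of interest, log-scale repeatability statistics (within-lesion SD and CV,
    repeatability coefficient, one-way intraclass correlation, Bland-Altman
    limits of agreement back-transformed to ratios), and paired log-normal
    sample-size calculations for detecting relative flow changes. Includes
    synthetic generators for paired log-normal measurement tables, arterial
    input functions, and 4-D dynamic phantoms with known kinetics.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
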