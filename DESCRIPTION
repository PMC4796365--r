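Package: constrictr
Title: Quantification of Cell Migration Through Microchannel Constrictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An image-analysis pipeline for microchannel constriction
    migration assays in two-channel fluorescence time-lapse movies
    (an F-actin reporter and a DNA stain). Segments cells and nuclei,
    tracks centres of mass and front/back edges, classifies the
    four-phase passage event (cell entry, nuclear entry, nuclear exit,
    cell exit), and computes normalized perinuclear actin-enrichment
    metrics, nuclear shape descriptors, and nuclear-lamina ring-gap
    morphometry from fixed-cell stills. Includes a calibrated synthetic
    movie generator with full ground truth so every stage of the
    measurement chain can be validated by parameter recovery, plus
    exact Fisher and Mann-Whitney tests for cohort comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    tiff,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
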