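Package: trophoquant
Title: Per-Cell Immunofluorescence Quantification for Trophoblast Differentiation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative single-cell analysis of immunofluorescence images from
    trophoblast stem cell differentiation experiments. Detects cells from the
    DAPI channel, assigns each cell a marker intensity from its nearest stain
    component with an isotype-control fallback rule, normalizes intensities to
    the isotype baseline, classifies cells as colony members or isolated single
    cells by a neighbor-radius rule, stratifies cells into expression quartiles
    with double-negative exclusion, computes the syncytial fusion index
    (N - S)/T, and provides the matching inference layer (large-sample
    Mann-Whitney U, an F-test-gated two-sample t test, and delta-delta-Ct qPCR
    fold changes). A synthetic-field generator produces ground-truthed
    fluorescence images and Ct tables so that the whole pipeline is testable
    without microscope data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    EBImage,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    tiff,
    png
Suggests:
    testthat (>= 3.0.0),
    withr,
    ggplot2
Config/testthat/edition: 3
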