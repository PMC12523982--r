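Package: qpihuvec
Title: Quantitative Phase Imaging Morphometry, Tubulogenesis and
    Pharmacology for Endothelial Cell Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free analysis of quantitative phase images of
    endothelial cell (HUVEC) monolayer and tube-formation assays.
    Segments optical-path-difference rasters into cells, applies a
    400 square-micron debris gate, and derives phase-specific
    morphology metrics (dry mass, optical thickness, sphericity,
    length-to-width ratio), optionally paired with co-registered
    fluorescence. Converts phase images of tube networks into
    skeleton-derived planar graphs and tubulogenesis metrics
    (segments, junctions, branches, extremities, network length).
    Fits three-parameter logistic concentration-response curves to
    derive potency (pEC50) and efficacy (span). A synthetic phantom
    generator produces phase images, tube-network scenes and
    dose-response tables with exact analytic ground truth, so every
    stage of the pipeline can be verified against known values.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    data.table,
    jsonlite,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
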