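Package: reec
Title: Diffusion-Consumption Modelling and Radial Profiling for
    Restricted Exchange Environment Chambers
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Models cell-generated oxygen and nutrient gradients in
    restricted exchange environment chambers (REECs): a finite-volume
    solver for the radially symmetric diffusion-consumption equation on
    the chamber annulus with saturating per-cell uptake kinetics,
    closed-form transport calculations (per-cell consumption rate
    constant, characteristic diffusion-consumption length, a Fick's-law
    column model for the aperture boundary concentration), a radial
    fluorescence quantification pipeline for segmented per-cell tables
    and raster images (annulus binning, normalization, moving-average
    smoothing, hypoxic-front detection, disk-area change, channel
    correlation, replicate aggregation), and a seeded generator of
    synthetic cell tables and images for testing the pipeline end to
    end without laboratory data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    deSolve,
    graphics,
    jsonlite,
    stats,
    tiff,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
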