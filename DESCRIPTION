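Package: endokin
Title: Kinetic and Nanoscale Analysis of Presynaptic Endocytosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantification pipeline for optical recordings of synaptic vesicle
    recycling and nanoscale synapse imaging. Fits endocytic decay constants (tau)
    to pHluorin and CypHer5E fluorescence traces with photobleaching correction,
    detects responding boutons in time-lapse videos, measures multicolor STED
    line profiles aligned to a presynaptic reference marker, summarises electron
    microscopy morphometry as densities per bouton area, and applies a
    normality-gated statistical decision scheme. Includes seeded synthetic-data
    generators for traces, videos, three-channel synapse images, and morphometry
    tables with known ground truth, so every analysis stage is testable without
    raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    tiff,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
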