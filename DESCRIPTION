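Package: fairyringr
Title: Process-Based Simulation of Fairy Ring Formation and Plant-Fungus
    Interactions
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the radial expansion of fairy-ring fungi and their
    effects on grassland vegetation with a system of six coupled
    reaction-diffusion equations (fungal biomass, a fungal self-inhibitor,
    phytotoxins, phytostimulants, plants and soil nutrients) on 1D transect
    or 2D lattice domains with zero-flux boundaries. Provides hypothesis
    presets (soil hydrophobicity, phytotoxicity, combined), extraction of
    biometric indicators from biomass transects (fungal peak, plant
    stimulation and inhibition, bare-zone width, ring width), a decision-tree
    classifier of the observed fairy-ring types, and one-at-a-time parameter
    sensitivity sweeps with Pearson correlation signs and fold changes.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pracma,
    withr,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
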