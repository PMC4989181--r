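Package: wormcars
Title: Quantification of CARS Microscopy Images of Yolk Lipoprotein
    Transport and Oocyte Lipid Delivery in C. elegans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Label-free quantification of coherent anti-Stokes Raman
    scattering (CARS) microscopy images of Caenorhabditis elegans.
    Segments secreted yolk-lipoprotein accumulations in the pseudocoelom
    by intensity-ratio thresholding, builds blob size-distribution and
    area-contribution curves, computes integrated per-oocyte CARS and
    two-photon GFP signals with developmental staging (-5 to -1),
    cylinder-model oocyte volumes, ovulation rates and per-transition
    lipid-delivery rates, and strain-level correlation reports. Includes
    a seeded synthetic worm-image and reproduction-assay generator with
    ground-truth masks so the full pipeline is testable end to end
    without raw microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    tiff,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
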