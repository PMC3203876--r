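Package: nichephylo
Title: Ecological Niche Evolution Analysis for Clades of Tropical Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative analyses of ecological niche
    evolution across a time-calibrated phylogeny: buffer-union estimation of
    geographic ranges and pairwise range overlap, extraction of climate
    values at occurrence localities with per-pair principal component
    comparisons, a minimal maximum-entropy suitability model with replicate
    averaging and AUC evaluation, niche overlap statistics (Schoener's D and
    the Hellinger-based I) with identity and background randomization tests,
    phylogenetic signal of climatic variables (quantitative convergence
    index and Blomberg's K), and age-range correlation of niche similarity.
    Includes a synthetic-data module that generates spatially autocorrelated
    climate-like raster layers, occurrences sampled from Gaussian
    suitability surfaces, and ultrametric trees with niche optima evolved
    under Brownian motion, so every stage can be exercised and calibrated
    without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    MASS,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    picante,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
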