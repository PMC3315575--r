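Package: mitoscreen
Title: High-Content Screening of Mitochondrial Content Versus Cell Size
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis pipeline for image-based chemical screens
    that quantify per-cell mitochondrial content in confluent endothelial
    monolayers. Provides a ground-truthed synthetic plate generator (weighted
    Voronoi cell geometry, clumped mitochondrial texture, illumination
    gradients, Poisson-Gaussian noise, planted compound effects), the image
    analysis chain (retrospective illumination correction, three-class Otsu
    background thresholding, watershed nuclei declumping, seeded-propagation
    cell boundary segmentation, nucleus-masked cytoplasm measurement),
    plate-level statistics (day-matched robust Z-scores against DMSO controls,
    Stouffer composite scores, toxicity filtering, hit calling, and
    classification of effects as size-proportional versus size-dissociated),
    and the small calculators behind common secondary assays (mtDNA/nuDNA
    copy-number ratios, delta-delta-Ct expression folds, and respiration
    fold-changes under alternative normalizations).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    ggplot2,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
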