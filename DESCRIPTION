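Package: specdiv
Title: Cross-Dimensional Plant Biodiversity Metrics from the Ground and the Sky
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes analogous plot-level metrics of taxonomic, trait,
    phylogenetic and spectral plant diversity, estimates spectral species
    from plot-scale imaging-spectroscopy cubes by k-medoids clustering with
    a cluster-validity ensemble, links ground metrics to spectral metrics
    with Bayesian multilevel and quantile regressions, and quantifies
    between-plot phylogenetic community dissimilarity (PCD).  Includes a
    synthetic-landscape generator (virtual species pools with traits
    evolved on a simulated phylogeny, cover-weighted mixtures of species
    reflectance spectra, soil and sensor noise) so the full pipeline is
    testable without field or airborne data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    cluster,
    randomForest,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    picante,
    phytools
Config/testthat/edition: 3
RoxygenNote: 7.3.3
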