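Package: nanophylo
Title: Phylogenetic Mapping of Snake Scale Nanostructure Characters
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classifies SEM-like images of snake oberhautchen cell surfaces
    into discrete nanostructure states (smooth, holes, straight channels,
    labyrinthine channels) with a contour-based geometric algorithm, then maps
    the resulting discrete characters on a time-calibrated phylogeny: Mk
    models (ER/SYM/ARD) with Pagel lambda/delta/kappa tree transformations and
    AICc model selection, a likelihood-ratio test of phylogenetic signal,
    stochastic character mapping by uniformization, and phylogenetic
    correlation tests (PGLS with pseudo-continuous coding and a Bayesian
    multinomial-logit phylogenetic mixed model). Includes a synthetic-data
    generator (ground-truth images, birth-death trees, Mk-simulated
    characters) so the whole pipeline is testable offline.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    EBImage,
    jsonlite,
    Matrix,
    png,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    nnet,
    phangorn,
    phytools,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
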