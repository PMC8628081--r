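Package: TEcoevo
Title: Individual-Based Simulation of Transposable Element and Host
    Genome Coevolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: An individual-based model of the coevolution of autonomous
    transposable elements (TEs) and the architecture of their host
    genomes.  Cells with linear genomes of essential genes, TEs and
    non-coding DNA live on a toroidal grid, compete locally for space in
    proportion to fitness, and exchange TEs horizontally through a pool
    of extracellular DNA released by cell lysis.  The package provides
    the genome, mutation, transposition, eDNA and population-dynamics
    primitives, a fast compiled simulation engine, lineage-level
    observers, and canned scenario runners for ecological phase sweeps,
    de novo genome-streamlining experiments, insertion-damage controls
    and sexual versus asexual comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
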