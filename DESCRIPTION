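Package: thermoprom
Title: Thermodynamic Modeling of Bacterial Promoter Function and Evolution
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Statistical-thermodynamic models of sigma70-RNA-polymerase
    binding that predict constitutive gene expression from arbitrary DNA
    sequence. Implements a Standard (single strongest site) and an Extended
    occupancy model (cumulative binding over flexible-spacer configurations,
    occlusive unproductive binding near the ribosome binding site, occlusive
    binding on the reverse complement, dinucleotide interactions, and a
    polymerase clearance rate), together with sort-seq library processing and
    spike-in debiasing, maximum-likelihood fitting of energy-matrix parameters
    from binned sort-seq data, a synthetic sort-seq data generator,
    strong-selection-weak-mutation promoter-evolution simulations with Kimura
    fixation, and genome-wide binding-energy scans with GC-matched and
    shuffled-matrix null tests for binding-site depletion.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    rtracklayer,
    BiocGenerics
Config/testthat/edition: 3
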