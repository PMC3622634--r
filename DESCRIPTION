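Package: mosaicAncestry
Title: De Novo Inference of Population Stratification and SNP-Resolution
    Local Ancestry
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Two-layer Bayesian Markov model for de novo inference of
    population stratification and local admixture from sequencing read
    counts, genotypes or phased haplotypes, without requiring reference
    ancestry. A first infinite-state Markov layer segments haplotypes into
    shared ancestral haplotype states; a second layer clusters the segments
    into an unknown number of populations under a stick-breaking prior,
    with Dirichlet-marginalized per-SNP admixture rates and explicit
    modelling of haplotype phasing switch errors. Includes an admixture
    simulator driven by a genetic map, Poisson read simulation, and the
    evaluation metrics (adjusted Rand index, per-SNP label mapping against
    references, local-ancestry error, per-SNP population counts).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite,
    vcfR
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mclust,
    optparse
Config/testthat/edition: 3
biocViews: PopulationGenetics, SNP, Bayesian, HiddenMarkovModel,
    Sequencing, Genetics
RoxygenNote: 7.3.3
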