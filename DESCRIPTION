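Package: famevol
Title: Gene-Family Evolutionary Analysis: Homology, Phylogeny, Duplication
    and Selection
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end, testable re-implementation of a plant
    gene-family molecular-evolution workflow: protein physicochemical
    characterization (molecular weight, isoelectric point, GRAVY,
    instability and aliphatic indices), reciprocal-best-hit family
    identification from exact Smith-Waterman scores, neighbor-joining
    phylogenies with bootstrap support from p-distances under pairwise
    deletion, gene-tree/species-tree reconciliation with old/recent
    duplication age classes and per-clade loss inference, pairwise
    Ka/Ks estimation by Nei-Gojobori counting and by maximum likelihood
    under the Goldman-Yang codon model, one-ratio versus two-ratio
    branch-model likelihood-ratio tests, IUPAC-degenerate promoter motif
    scanning with SNP region classification, RPKM and 2^-ddCt expression
    summaries with hierarchical clustering, and simulators (gene-family
    birth-death, codon evolution, promoters, count/Ct tables) that
    provide ground-truth event logs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    GenomicRanges,
    rtracklayer,
    ape,
    phangorn
Suggests:
    testthat (>= 3.0.0),
    withr,
    Matrix,
    jsonlite,
    optparse,
    yaml,
    knitr,
    rmarkdown
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
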