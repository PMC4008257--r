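Package: treeplacer
Title: Two-Tier Phylogenetic Placement of Unsampled Taxa on Backbone Trees
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for placing previously unsampled taxa into large fixed
    phylogenies with a two-tiered workflow: saturation screening of supermatrix
    partitions from paired uncorrected and model-corrected patristic distances,
    constrained maximum-likelihood placement of query taxa on a backbone tree
    under partitioned GTR/HKY models with discrete-Gamma rate heterogeneity,
    nonparametric bootstrap placement tallies with rogue-aware effective support
    and cumulative region support, focused subset selection, and adjudication of
    competing placement hypotheses with RELL-based approximately unbiased (AU)
    topology tests. Includes a seeded synthetic-study generator emulating
    multi-gene supermatrices with block-structured missing data, heterogeneous
    partition rates and saturated mitochondrial third codon positions, so the
    whole workflow is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape (>= 5.0),
    jsonlite,
    Rcpp,
    seqinr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    Matrix,
    phangorn,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
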