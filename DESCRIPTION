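Package: tii
Title: Bayesian Taxon Influence Index from Posterior Tree Samples
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies how strongly each taxon in a phylogenetic data set
    shapes the inferred relationships among the remaining taxa. The taxon
    influence index (TII) of a taxon is the expected tree distance between
    the full-data Bayesian posterior of topologies (with the focal taxon
    pruned a posteriori) and the posterior re-inferred after jackknifing
    that taxon out of the data matrix. Distances are measured by the SPR
    excess: the subtree-prune-and-regraft distance scaled by the size of
    the maximum agreement subtree, so that disagreement is judged relative
    to the part of the tree the two posteriors share. Includes exact and
    resampling estimators of the index with uncertainty summaries, exact
    (breadth-first search) and heuristic SPR distances, maximum agreement
    subtree computation, Robinson-Foulds and branch-score comparators,
    rank-biased overlap with a permutation test for comparing taxon
    rankings, jackknife matrix preparation, and a seeded synthetic
    posterior generator for validation. A command-line interface covers
    the full pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    phangorn,
    jsonlite,
    stats,
    utils,
    graphics,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
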