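Package: ciliaprofile
Title: Phylogenetic Profiling of Ciliary Genes Across Eukaryotic Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for gene-level phylogenetic profiling: reciprocal-best-hit
    orthology calls from tabular alignment output, construction of binary
    presence/absence matrices across genomes, hierarchical co-clustering with
    deterministic average linkage, ciliated-left dendrogram leaf ordering,
    seed-anchored cluster extraction with species-subsampling robustness,
    Dollo-parsimony counting of independent cilium losses on a species tree,
    footprint-based prediction of cilium biogenesis versus motility function,
    phenotype-screen scoring rubrics for fly and worm assays, and a synthetic
    evolution simulator that plants co-lost gene modules on a species tree so
    the whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
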