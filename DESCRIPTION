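Package: phylortho
Title: Orthology Inference from Gene Trees by Species Overlap and
    Markov Clustering
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers pairs and clusters of orthologous genes (orthogroups)
    from a precomputed, species-labeled gene tree. Internal nodes are
    classified as speciations or duplications with the species-overlap
    heuristic, ortholog pairs are assembled into a support-weighted graph,
    and the graph is partitioned into orthogroups with Markov clustering
    (MCL). Includes midpoint and parsimony-guided iterative rooting,
    reference-based gene and orthogroup naming with phylogeny-aware
    label propagation, ortholog/in-paralog/out-paralog pair
    classification, benchmarking metrics (precision, recall, F-score,
    adjusted Rand index, tip randomization), and a duplication-loss
    simulator that generates gene trees with known orthogroup truth.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.0)
Imports:
    ape,
    phytools,
    stats,
    utils
Suggests:
    jsonlite,
    mclust,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
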