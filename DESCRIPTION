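Package: lepin
Title: Protein Complex Detection from Supervised Weighted Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for building protein complex catalogues from protein
    interaction networks. Augments an interactome with candidate interactions
    recovered by a hypergeometric co-occurrence model and by degree-normalized
    length-3 path (L3) link prediction, computes per-edge annotation features
    (subcellular localization, Pfam domains, chain length, GO similarity),
    weights every edge with the probability that it lies within a complex (a
    supervised c-edge/nc-edge classifier trained with sub-sampled 10-fold
    cross-validation), and detects complexes from the weighted network by a
    density-plus-modularity score maximized with a seeded inflate/shrink
    search ordered by k-shell decomposition. Includes the standard
    complex-prediction evaluation metrics (matching rate,
    Recall/Precision/F-measure, maximum matching ratio, geometric accuracy),
    downstream calling of multifunctional proteins and affected complexes,
    and deterministic synthetic-network generators with planted complexes for
    end-to-end testing.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    ranger,
    parallel,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
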