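Package: assemblyscope
Title: Null-Model Inference of Microbial Community Assembly Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the balance of deterministic and stochastic
    processes shaping microbial (e.g., soil fungal) communities from an
    OTU/ASV count table, a rooted phylogeny and sample metadata.
    Implements phylogenetic and taxonomic alpha- and beta-diversity
    (Shannon, Faith's PD, Bray-Curtis, beta mean nearest taxon distance),
    the beta nearest taxon index (betaNTI) and Bray-Curtis-based
    Raup-Crick (RC_bray) null models with the five-way ecological process
    classification, the normalized stochasticity ratio (NST), the Sloan
    neutral community model, Levins' niche breadth, phylogenetic-signal
    Mantel correlograms, and co-association networks thresholded by
    random matrix theory with Zi-Pi node roles and degree-preserving
    random-network comparisons.  A synthetic community simulator with
    known assembly regimes (neutral, selection, dispersal limitation)
    provides ground truth for every stage.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    vegan,
    picante,
    phangorn,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    biomformat,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
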