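Package: cipherhit
Title: Hitting-Time Inference on Phenotype-Gene Heterogeneous Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds a weighted heterogeneous network from a protein-protein
    interaction network, a phenotype-phenotype similarity network and
    gene-phenotype associations, and performs parameter-light random-walk
    inference on it. Closeness between nodes is measured by the scaled
    mean hitting time of the random walk, and by a conditional mean
    hitting time (computed through the harmonic potential and a Doob
    h-transform) that excludes walks through a chosen avoid set. On top of
    these measures the package ranks candidate disease genes for a target
    phenotype, scores the modularity of the phenotype's adjacent nodes,
    flags credible predictions whose rank improves when only the modular
    adjacent nodes are used as references, clusters prioritized genes into
    candidate disease-subtype sub-modules, and validates predictions by
    genome-wide leave-one-out cross-validation with ROC summaries and a
    random-walk-with-restart baseline. A seeded synthetic-network
    generator with planted modules and subtypes supports testing without
    external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    igraph,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    methods
Suggests:
    cluster,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
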