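Package: foldphylo
Title: Structure-Based Phylogenetics and Virion Geometry for Viral Capsid Proteins
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Sequence-independent, structure-based phylogenetic analysis of
    viral capsid proteins. Reads atomic coordinate files (PDB/mmCIF),
    extracts C-alpha traces of jelly-roll fold cores, performs pairwise and
    progressive multiple rigid-body superposition (Kabsch algorithm with an
    iterative dynamic-programming correspondence search), assembles all-vs-all
    RMSD distance matrices, and builds neighbor-joining trees with clade
    (monophyly) tests. Also provides quantitative geometry of icosahedral
    capsid lattices (triangulation numbers, subunit counts) and of solenoidal
    ("spooled") genome layers (base-pair capacity, radius inversion, helix
    traces, turn-spacing measurement), and a synthetic-data generator that
    evolves compact C-alpha backbones along a known tree for end-to-end
    parameter-recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    ape,
    bio3d,
    Rcpp,
    stats,
    tibble,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    jsonlite,
    knitr,
    optparse,
    phangorn,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
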