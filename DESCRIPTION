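Package: coopbalance
Title: Compositional Microbiome-Phenotype Association via Nearest Balances and Co-Abundance Cooperatives
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Compositional analysis of taxon count tables against clinical
    covariates. Implements centred log-ratio geometry (Aitchison distance,
    principal-coordinate biplots, alpha diversity), the nearest-balance method
    with cross-validated reproducibility screening, sparse co-abundance network
    inference by stability-selected neighbourhood selection with Louvain
    community detection ("cooperatives"), permutation tests for beta diversity
    (PERMANOVA and distance-based redundancy analysis), per-rank log-ratio
    association screens with Benjamini-Hochberg control, and a synthetic cohort
    generator with planted ground truth for method validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    glmnet,
    igraph,
    stats,
    utils,
    yaml,
    jsonlite,
    biomformat
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
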