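Package: lncrank
Title: Multi-Network Prioritization of Cancer-Associated lncRNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Prioritizes candidate long non-coding RNAs (lncRNAs) for a
    cancer type by propagating a set of known cancer lncRNAs through
    several heterogeneous lncRNA-centric networks with random walk with
    restart, then fusing the per-network ranks with node topology
    (betweenness, degree, network coverage) into a single overall score
    per candidate. Includes builders for the underlying network types
    (co-expression, functional similarity, ceRNA, sequence similarity,
    interaction networks), a leave-one-out cross-validation and ROC/AUC
    evaluation protocol, robustness experiments, and a synthetic data
    generator with planted disease modules so the whole pipeline runs
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    purrr,
    rlang,
    readr,
    Matrix,
    igraph,
    ggplot2,
    generics,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
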