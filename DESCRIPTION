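Package: phenomatch
Title: Cross-Species Phenotype Similarity for Identifying Mouse Models of
    Mendelian Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Automated identification of mouse disease models by
    cross-species phenotype comparison. Parses a merged human (HPO-like)
    and mouse (MP-like) phenotype ontology, computes annotation-based
    information content and most-informative common ancestors, and scores
    mouse knockout models against Mendelian diseases with a
    PhenoDigm-style percentage score normalised by the disease
    self-comparison optimum. Includes readers for model, disease and
    ortholog catalogues with a bidirectional one-to-one ortholog filter,
    gene-level aggregation with novelty calling against an external model
    catalogue and a lethality-based rescue rule, an association layer
    (category enrichment, rank tests, correlations and logistic
    regression of match status), and a seeded synthetic-study generator
    with planted statistical structure for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
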