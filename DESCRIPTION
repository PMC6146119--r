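Package: autolit
Title: Literature Mining of Autophagy-Disease Associations and
    Positive-Unlabeled Gene Prioritization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dictionary-based scanning of a biomedical literature
    corpus against a disease lexicon, concentration- and retention-ratio
    statistics of disease-class composition, pairwise disease-class
    association by a cumulative hypergeometric co-mention test with module
    extraction, positive-unlabeled gene scoring by bagged negative
    resampling with random forests (frequency-of-positive-call possibility
    scores), and information-content-based Lin semantic similarity over a
    minimal ontology for function-consistency validation of predicted gene
    sets. Includes seeded synthetic-data generators that emulate the
    statistical structure each stage assumes, so every stage is testable
    end to end without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    ranger,
    rlang (>= 1.0.0),
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
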