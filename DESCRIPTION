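Package: noduleaudit
Title: Quality Auditing of Pulmonary-Nodule Radiology Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts pulmonary-nodule entities from free-text radiology
    report findings with a bidirectional LSTM + linear-chain CRF sequence
    labeler, normalizes mentions to a canonical nodule state (name,
    solidity, size, quantity, risk), generates a Fleischner-style
    follow-up recommendation by traversing a guideline knowledge graph,
    and audits written impressions against the generated recommendation
    to produce per-level and overall matching rates. Includes a seeded
    synthetic-corpus generator with gold annotations for end-to-end
    evaluation, CoNLL-style BIO and JSONL corpus input/output, and
    Cypher/GraphML graph export.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    dplyr,
    tidyr,
    purrr,
    tibble,
    rlang,
    jsonlite,
    yaml,
    igraph,
    ggplot2,
    generics,
    withr,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
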