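Package: spbacrf
Title: Gene and Protein Mention Recognition with Concept Patterns and
    Conditional Random Fields
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognizes gene- and protein-related object (GPRO) mentions in
    patent-style biomedical text. Combines a statistical principle-based
    approach (SPBA) -- concept-knowledge-base dictionary labeling, pattern
    induction from gold mentions, approximate pattern matching with
    insertion/deletion tolerance and logistic scoring -- with a linear-chain
    conditional random field sequence tagger over sub-tokens using the SOBIE
    tag scheme. Includes rule-based span/type post-processing (identifier
    mapping, document tag consistency, annotation-standard span rules,
    blacklist filtering), strict and relaxed span evaluation, and a
    deterministic synthetic-fixture generator so the whole pipeline trains
    and tests offline.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
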