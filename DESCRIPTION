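Package: atldisc
Title: Discriminant Temporal-Relation Analysis of Annotated Event Sequences
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for discovering class-discriminant temporal structure in
    interval-annotated behavioural sequences, developed for the study of
    nonmanual grammatical markers (face and head articulations) in sign
    language. Annotated sentences are encoded as occurrence-count histograms
    over epsilon-tolerant Allen interval relations (before, meets, overlaps,
    equals, starts, during, finishes) between articulator events, restricted
    to relations feasible under articulator mutual exclusivity. Regularized
    linear discriminant analysis ranks relations by discriminative weight;
    leave-one-sentence-out nearest-mean classification, per-relation
    activation rates, d-prime sensitivity, one-dimensional classification
    accuracy and label-permutation significance testing validate the ranking.
    Includes an ELAN EAF reader, a lossless tabular interval format, and a
    synthetic corpus generator with class-conditional temporal grammars.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    xml2,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
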