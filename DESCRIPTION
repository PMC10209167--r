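Package: pwas
Title: Publication-Wide Association Studies with Time-Sliced Word Embeddings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Trains continuous bag-of-words and skip-gram embedding models on
    time-sliced, entity-canonicalized literature corpora and uses them to rank
    gene-disease associations, protein-protein interactions and drug-target
    pairs prospectively. Includes dictionary-based entity canonicalization,
    NPMI phrase mining, historical corpus slicing, embedding training with
    negative sampling, genome-wide association rankings with bootstrap
    baselines and positive-unlabeled prospective evaluation, contextual
    linking words, clinical-stage score regression, promiscuity-stratified
    drug-target metrics, motif-enrichment druggability scoring, and a
    synthetic literature generator with planted ground truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    randomForest,
    cluster
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
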