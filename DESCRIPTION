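Package: clonemem
Title: Transcriptional Memory and Transgenerational Plasticity in Clonal Plants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for multi-generation stress-priming experiments in
    clonally propagated plants. Implements negative-binomial differential
    expression against a common control, three-step identification of
    transcriptional memory genes across stress, recovery and re-exposure
    generations, classification of phenotypic traits into weaken/strengthen
    reaction-norm types via Fisher's LSD, weighted co-expression network
    construction with topological overlap, module eigengenes, module-trait
    association and hub-gene detection, and relative qPCR quantification by
    the 2^-ddCt method. A seeded synthetic-data generator plants
    memory-gene classes and coupled trait reaction norms so that every stage
    of the pipeline can be validated against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    withr
Suggests:
    DESeq2,
    mclust,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
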