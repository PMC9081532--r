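Package: sigtrace
Title: Mutational-Signature-Based Tumor Detection and Tissue-of-Origin Tracing
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Builds 96-channel trinucleotide substitution spectra from somatic
    SNV calls, refits spectra against a reference signature catalog by
    forward-selection non-negative least squares, extracts de novo signatures
    by non-negative matrix factorization and maps them to the catalog by
    cosine similarity, selects cancer-type-specific signature patterns and
    tumor-specific mutation markers, trains per-type one-vs-rest stepwise
    logistic classifiers and a two-stage metastatic tissue-of-origin cascade,
    scores protein-interaction connectivity of mutated gene sets, quantifies
    primary-metastasis signature concordance, and simulates labeled synthetic
    cohorts (tissue, metastasis, and diluted cfDNA compartments) with known
    ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    nnet,
    pracma,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
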