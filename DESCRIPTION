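Package: ntaug
Title: Nucleotide Augmentation for Machine Learning on Protein Sequence-Function Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Expands labeled protein sequence datasets by reverse-translating
    amino acid sequences into multiple synonymous nucleotide sequences via
    codon degeneracy (nucleotide augmentation, NTA). Provides offline
    iterative, offline random, and online probabilistic augmentation over
    natural, balanced, and shuffled amino-acid-to-codon tables; ngram
    (unigram, trigram, tri+unigram) tokenization with categorical and one-hot
    encodings; data-handling protocols for edit-distance train/test
    splitting, stratified truncation, class imbalancing, minority-class
    augmentation and replicated test-set reverse translation; synthetic
    combinatorial-mutagenesis fitness landscapes and binder libraries;
    reference convolutional and transformer-encoder regressors/classifiers
    trained by stochastic gradient descent with momentum; and Spearman/MCC
    evaluation with replicate- and seed-level aggregation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    jsonlite,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
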