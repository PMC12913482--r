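Package: PhageHostNet
Title: Dual-Tower Deep Learning for Phage-Host Interaction Prediction
        from Genome Sequences
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org",
        role = c("aut", "cre"))
Description: Implements a pseudo-Siamese (dual-tower) neural framework for
    predicting bacteriophage-bacterial host interactions directly from whole
    genome sequences. Genomes are segmented into fixed 2 kb windows, tokenized
    into overlapping k-mers and embedded with a skip-gram model; each segment
    is encoded by a convolutional tower and segment vectors are aggregated
    across the genome by a Transformer encoder with a learnable CLS vector.
    A fused multilayer perceptron scores each phage-host pair as match or
    non-match. The package ships a synthetic phage-host genome generator with
    clade-specific k-mer compositional biases and phylum-exclusion negative
    sampling, training utilities (Adam, L2 regularization, gradient clipping,
    batch-norm moving statistics), host ranking, and five-rank hierarchical
    accuracy evaluation (genus to phylum).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports: methods, stats, utils, tools, Rcpp, jsonlite, yaml, Biostrings,
        S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
biocViews: Sequencing, Classification, MachineLearning, Metagenomics
RoxygenNote: 7.3.3
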