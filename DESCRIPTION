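Package: aptabind
Title: Aptamer-Protein Interaction Prediction and Candidate Aptamer Design
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts aptamer-protein interactions (API) at the monomer level
    with paired transformer encoders whose per-token embeddings are combined
    into a dot-product interaction map and scored by a residual convolutional
    network. Aptamer (RNA) sequences are tokenized as overlapping k-mers and
    protein sequences with a mined frequent-consecutive-subsequence (FCS)
    subword vocabulary. Encoders can be pretrained with two self-supervised
    tasks, masked-token prediction and secondary-structure prediction, before
    fine-tuning on labelled pairs with symmetric-aptamer augmentation.
    Candidate aptamers for a target protein are designed by Monte Carlo tree
    search (UCB1) over nucleotide space using the predictor as the reward.
    Includes deterministic synthetic-data generators for desk-scale corpora
    and labelled pair datasets with a planted, recoverable binding rule.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    Rcpp,
    jsonlite,
    optparse,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
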