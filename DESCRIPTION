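Package: deep5mC
Title: Attention-Augmented Convolutional-Recurrent Prediction of Promoter
    5-Methylcytosine Sites
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts 5-methylcytosine (5mC) sites in promoter regions from
    41-bp DNA windows centred on a candidate cytosine. Sequences are encoded
    as one-hot and nucleotide-chemical-property (NCP) feature matrices and
    classified by a densely connected convolutional network augmented with
    convolutional block attention (CBAM), followed by a bidirectional GRU,
    self-attention pooling and a softmax head. Includes class-weighted
    training for heavily imbalanced data, stratified splitting and k-fold
    cross-validation, confusion-matrix metrics (Sn, Sp, Acc, MCC, F1,
    ROC-AUC, PR-AUC), and a synthetic benchmark generator that plants a
    degenerate motif in 41-bp windows at a configurable class imbalance.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Biostrings,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
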