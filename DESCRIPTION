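Package: piRBind
Title: Identifying piRNA Target Sites on mRNAs with a Deep Multi-Head
    Attention Network
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Constructs experimentally verified positive and negative
    piRNA-mRNA pair sets from CLASH chimeric reads (chimera splitting
    against a piRNA catalog, transcriptome mapping, rigorous and loose
    filtering rules, complement-based negative sampling) and trains a deep
    multi-head attention network - convolution plus squeeze-and-excitation
    motif extraction, site-by-site attention between mRNA and piRNA
    positions, a residual feed-forward block and a fully connected
    classifier - to discriminate true binding pairs. Includes a pure-CNN
    ablation, whole-sequence feature baselines with an MLP, ROC/AUC
    evaluation with rank-sum model comparison, attention-weight
    binding-rule extraction, and a synthetic-data generator with planted
    seed-rule target sites.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    grDevices,
    graphics,
    Rcpp,
    jsonlite,
    Biostrings
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = FALSE)
RoxygenNote: 7.3.3
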