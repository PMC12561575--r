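Package: slenet
Title: Estrous-Cycle Stage Classification from Vaginal Cytology Images with
    Channel-Spatial and Non-Local Attention Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to classify the four stages of the rat estrous cycle
    (proestrus, estrus, metestrus, diestrus) from stained vaginal-smear
    microscopy images. Implements a compound-scaled mobile inverted-bottleneck
    (MBConv) convolutional backbone in which squeeze-and-excitation attention
    is replaced by a joint channel-spatial attention block (SECA) and whose
    head carries a non-local self-attention block; training with AdamW and
    early stopping; bicubic image rescaling from the cubic-convolution kernel;
    stochastic brightness/contrast/flip/rotation augmentation; multiclass
    evaluation statistics (confusion matrices, one-vs-rest ROC/AUC and
    precision-recall/AP, multi-seed confidence intervals and paired tests);
    analytic parameter and floating-point-operation accounting; and a
    synthetic vaginal-cytology image simulator so the full pipeline can be
    exercised with labeled data generated in code.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    png,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    EBImage,
    yaml
Config/testthat/edition: 3
NeedsCompilation: yes
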