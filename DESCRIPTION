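Package: efnet
Title: Ejection Fraction Estimation from Echocardiogram Videos with a
    3D Residual Transformer Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end estimation of left-ventricular ejection fraction (EF)
    from echocardiogram cine loops. Implements a 3D ResNet-18 video-regression
    backbone in which the residual blocks of two stages are replaced by
    Residual Transformer Modules: 3D multi-head self-attention with a learned
    relative positional encoding decomposed into temporal, height and width
    tables. Includes a reader/writer for the EchoNet-Dynamic directory layout
    (uncompressed AVI cine loops plus CSV manifests), a synthetic ultrasound
    phantom generator with analytically known EF, clip-level training
    augmentations, a seeded Adam/MSE training loop with step learning-rate
    decay, segment-averaged patient-level inference, and the standard
    regression metric suite (MSE, RMSE, MAE, MAPE, R-squared, F1 for EF
    below 40 percent). The network forward and backward passes are
    implemented from first principles on CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
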