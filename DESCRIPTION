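Package: ihiscore
Title: Automatic Rating of Incomplete Hippocampal Inversion from Grey-Matter Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to automate the visual rating of incomplete hippocampal
    inversion (IHI) from spatially normalized grey-matter probability maps.
    Four ordinal anatomical criteria (hippocampal-body verticality and
    roundness, collateral-sulcus depth, medial position, fusiform sulci) are
    predicted by 3D convolutional regressors (conv5-FC3, a 3D ResNet, a
    squeeze-and-excite ResNet) or a ridge baseline, rounded to their rating
    grids and summed into an interpretable composite score (IHI when the
    composite is 4 or more). Includes a Kolmogorov-Smirnov-stratified
    train/validation/test split search, intraclass-correlation and
    weighted-kappa agreement statistics with paired-bootstrap method
    comparison, and a synthetic hippocampus phantom generator with known
    ground-truth criteria so the whole pipeline can be exercised without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    glmnet,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
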