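Package: lungfissure
Title: Automated Pulmonary Fissure Integrity Assessment from Lung CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies pulmonary fissure completeness (fissure integrity)
    from lung CT. Given a CT volume, lung mask, five-lobe segmentation and a
    fissure probability map, the package extracts the complete lobar boundary
    surface, classifies every boundary voxel as intact or incomplete fissure
    with a 3D attention U-Net trained under a Tversky loss, cleans the labeling
    with morphological majority-vote post-processing, and reports the fissure
    integrity percentage (FI%) together with accuracy, error and ROC metrics.
    Includes a synthetic thoracic phantom generator with controllable fissure
    gap fractions so that training, post-processing and evaluation can be
    exercised end to end without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
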