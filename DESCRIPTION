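Package: imiomics
Title: Voxel-Wise Whole-Body Composition Mapping with Carotid Wall Associations
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for voxel-wise ("Imiomics"-style) analysis of whole-body
    water-fat MRI against carotid ultrasound wall measures. Provides a
    calibrated synthetic-cohort and body-phantom generator with ground-truth
    deformation fields; tissue-sequential (bone, water, fat) constrained
    deformable registration to a reference with Jacobian local-volume maps;
    voxel-wise Spearman and partial-correlation maps with the standard
    rendering conventions; atlas-propagated visceral and subcutaneous
    adipose-tissue quantification with fat-fraction thresholding; automated
    carotid intima-media thickness and grey-scale-median extraction from
    B-mode-like frames; and sex-stratified SD-standardized regression tables
    with risk-factor and Framingham-score adjustment.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Matrix,
    Rcpp,
    RNifti,
    jsonlite,
    png
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
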