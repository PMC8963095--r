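Package: fissureseg
Title: Cerebellar Fissure Segmentation with an Inception U-Net
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for segmenting cerebellar fissures in T1-weighted
    MRI. Provides a semi-automatic label-construction procedure that derives three
    binary masks (fissures only, tissue with fissures carved out, and the whole
    cerebellum) from a registered volume plus a cerebellar mask; a 3D U-Net built
    from inception modules with instance normalization, trained with a soft-Dice
    objective and rigid-motion data augmentation; volumetric evaluation metrics
    (Dice, overlap coefficient, specificity, sensitivity, balanced-accuracy AUC);
    and a synthetic cerebellum phantom generator so the whole pipeline can be
    exercised without access to clinical data.
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
    testthat (>= 3.0.0),
    yaml,
    optparse,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
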