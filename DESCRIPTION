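Package: striatomics
Title: Radiomic Analysis of Striatal FDOPA PET with Synthetic Phantoms
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for texture-based analysis of striatal FDOPA PET volumes:
    40% SUVmax isocontour segmentation with largest-component retention,
    extraction of 43 shape, first-order and texture features (GLCM, GLRLM,
    NGLDM, GLZLM) under a 21-combination grid of grey-level, co-occurrence
    distance and voxel-size pre-processing parameters, feature-robustness
    analysis (Lin's concordance correlation coefficient, averaged Pearson
    correlation matrices), and bootstrap-LASSO feature selection with
    cross-validated regularisation leading to simplified logistic
    classifiers. Includes a calibrated synthetic striatal phantom generator
    so the full pipeline runs end-to-end without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
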