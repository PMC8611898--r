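Package: relmap3d
Title: Comprehensible 3D Convolutional Networks with Relevance Maps for
    Dementia Detection
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trains small 3D convolutional neural networks on gray-matter
    density volumes to separate dementia patients from controls, and explains
    their decisions with layer-wise relevance propagation (LRP) implemented
    from scratch (alpha-beta rule on convolutions, epsilon rule on dense
    layers). Includes covariate residualization of voxel intensities and
    scalar volumetry (age, sex, total intracranial volume, field strength),
    data augmentation, stratified cross-validation, atlas-based relevance
    aggregation, cluster extraction, occlusion sensitivity scanning,
    ROC/Youden evaluation against a hippocampus-volume baseline, and a
    synthetic brain-phantom cohort generator so the whole pipeline runs
    without access-restricted MRI data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
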