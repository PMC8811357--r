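Package: cmbselect
Title: Automated Preselection of Subjects with Cerebral Microbleeds on
    SWI/T2*-GRE MRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fully automated pipeline for preselecting candidate subjects
    with cerebral microbleeds (CMBs) from susceptibility-weighted or
    T2*-gradient-echo brain MRI. The pipeline removes elongated dark
    mimics (vessels, sulci) using Frangi vesselness and structure-tensor
    features with unsupervised clustering and nearest-neighbour
    inpainting, detects initial CMB candidate voxels with a seven-feature
    support-vector classifier, filters candidates by physical shape
    descriptors (volume, ellipticity, solidity, diameter), and calls a
    subject CMB-positive when the surviving candidate count exceeds a
    threshold. Includes subject-level ROC and cluster-wise FROC
    evaluation, and a seed-reproducible synthetic phantom generator that
    emulates SWI-like volumes with microbleeds and their mimics for
    training and benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    EBImage,
    e1071,
    pracma,
    yaml,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
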