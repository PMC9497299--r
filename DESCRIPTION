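Package: stapleseg
Title: Consensus Contouring, Inter-Observer Variability and SUV-Threshold
    Segmentation for PET Delineation Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing multi-observer tumour delineation studies on
    co-registered PET volumes. Implements binary STAPLE (simultaneous truth and
    performance level estimation), an expectation-maximization estimator that
    fuses several observers' binary contours into a probabilistic consensus
    while estimating each observer's sensitivity and specificity; contour
    agreement metrics (Dice coefficient, Hausdorff distance in mm, volume in
    cm^3); SUVmax-percentage threshold segmentation of PET lesions with
    connected-component growth and a full threshold sweep selecting the
    Dice-maximizing cutoff; paired Wilcoxon and Spearman analyses of
    inter-observer variability between imaging conditions; and a synthetic
    phantom plus simulated-observer generator so the whole pipeline can be
    exercised without patient data. Volumes and masks are read and written as
    3-D NIfTI files on a shared voxel grid.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    yaml,
    stats,
    graphics,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
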