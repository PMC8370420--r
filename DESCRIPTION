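Package: neorsn
Title: Neonatal Resting-State Network Analysis by Group ICA, Dual
    Regression and Permutation Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of neonatal resting-state functional MRI:
    DVARS-based motion QC with continuous low-motion window cropping, group
    independent component analysis by temporal concatenation, dual regression
    to subject level, voxelwise general linear models with Freedman-Lane
    permutation and threshold-free cluster enhancement (TFCE) family-wise
    error control, core-network-strength statistics (partial Spearman
    association with postmenstrual age, term versus preterm group tests,
    percent reduction), and winner-takes-all functional parcellation. A
    synthetic-cohort generator with known network maps, covariate-linked
    amplitudes and motion spikes provides ground truth for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    optparse,
    oro.nifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
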