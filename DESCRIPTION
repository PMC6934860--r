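Package: spheroMDR
Title: Multidrug-Resistance Profiling of Tumor Spheroids from Imaging,
    Viability and Flow-Cytometry Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: An integrated pipeline for profiling the multidrug-resistance
    (MDR) status of cancer cell lines from multicellular tumor spheroid
    (MCS) assays. Provides a seeded synthetic-data generator for
    time-lapse fluorescence stacks, MTS viability plates and
    flow-cytometry event tables; a dilated fully convolutional network
    for spheroid segmentation with a classical thresholding baseline;
    calcein-AM uptake and DCFDA/ROS kinetics quantification; four
    parameter logistic dose-response fitting with profile-likelihood
    IC50 confidence intervals; propidium-iodide gating and efflux-pump
    inhibitor retention analysis; and an evidence-combination rule that
    classifies each cell line as treatment sensitive, moderately
    resistant or highly resistant.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    jsonlite,
    minpack.lm,
    pracma,
    Rcpp,
    stats,
    tiff,
    utils,
    withr,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    ggplot2,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
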