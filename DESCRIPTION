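Package: qdcnn
Title: Accelerated Quantitative T2 Mapping with Unrolled Data-Consistent Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end framework for quantitative T2 and S0 mapping from
    undersampled multi-echo spin-echo MRI. Couples an unrolled, data-consistent
    convolutional reconstruction network with a pixel-wise fully connected
    mapping network trained jointly under image, parameter-map and k-space
    data-consistency losses. Includes a digital-phantom simulation pipeline
    (tissue-labelled brain-like phantoms, mono-exponential multi-echo signal
    synthesis, calibrated complex Gaussian k-space noise, retrospective
    Cartesian variable-density undersampling), classical variable-projection
    least-squares fitting baselines, NRMSE/PSNR evaluation over a foreground
    region, and experiment orchestration across acceleration factors and echo
    counts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    tibble,
    ggplot2,
    rlang,
    Rcpp,
    RNifti
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    dplyr
Config/testthat/edition: 3
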