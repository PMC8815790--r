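Package: caUnmix
Title: Targeted Non-Negative Matrix Factorization Unmixing of Calcium Imaging Traces
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Decontaminates per-neuron fluorescence traces from calcium imaging
    videos. For each segmented neuron the package builds auxiliary background and
    outside regions, subtracts the local background trace, and unmixes the
    neuron's trace from its neighbors and surround with a targeted non-negative
    matrix factorization whose regularization weight is lowered automatically
    until no separated trace collapses to zero. Also provides signal-to-noise
    ratio video generation (homomorphic spatial filtering, matched temporal
    filtering, per-pixel whitening), calcium-transient detection by SNR
    thresholding with peak-prominence screening, Hungarian-assignment scoring of
    detected transients against ground truth (precision, recall, F1), mask
    matching by intersection-over-union, leave-one-out cross-validation over the
    detection threshold and regularization weight, and a seeded synthetic video
    and trace simulator for offline validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    parallel,
    tiff,
    rhdf5,
    clue,
    pracma,
    yaml,
    jsonlite,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
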