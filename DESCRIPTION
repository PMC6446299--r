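Package: bofem
Title: Bi-Objective-Function Particle Picking and Verification for Cryo-EM
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Signal detection in low-contrast cryo-electron micrographs by a
    bi-objective-function (BOF) strategy: template-matching particle picking
    with the fast local correlation (FLC) function, followed by independent
    particle verification through multi-reference maximum-likelihood 2D
    alignment optimized by expectation-maximization. Includes a controlled-SNR
    micrograph simulator (phantom projections, parametric contrast transfer
    function, Gaussian noise scaled to a target variance-ratio SNR), MRC2014
    image input/output, and the quantitative readouts used to characterize
    picking robustness: false-positive rates against ground truth, ranked
    correlation-peak drop-off detection, Fourier ring correlation with FRC-0.5
    crossing frequency, rotationally averaged power spectra and spectral
    signal-to-noise ratios.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    yaml,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
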