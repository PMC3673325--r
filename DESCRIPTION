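Package: ecgbaseline
Title: Hierarchical Baseline Wander Removal for Single-Channel ECG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Removes baseline wander from single-channel electrocardiogram
    recordings by a hierarchical blind-source-separation method: an adaptive
    least-mean-squares notch filter isolates a low-frequency sub-signal,
    delayed copies of that sub-signal form a pseudo-multichannel matrix,
    fixed-point independent component analysis (negentropy contrast, deflation)
    extracts a baseline-wander component, and an affine shift/elevation/gain
    adjustment refines the estimate before subtraction.  Includes analytic
    notch-filter design formulas (transfer function, bandwidth), a robust
    locally weighted regression reference method, mean-squared-error reduction
    metrics, a synthetic ECG generator with ground-truth wander for validation,
    and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
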