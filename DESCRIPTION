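Package: mlpmotion
Title: Adaptive Motion-Coherence Thresholding and Stimulation-Study Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for adaptive estimation of motion-coherence thresholds with
    a maximum-likelihood procedure (MLP) over a fixed grid of logistic
    psychometric functions, including an interleaved two-hemifield session
    engine, a frame-level random-dot-kinematogram (RDK) simulator, simulated
    observers and synthetic cohorts with within-subject design structure, the
    group-level statistical plan of a three-condition stimulation study
    (one-tailed paired t-tests, within-subject ANOVA, exact noncentral-t
    power analysis), and a rank-based mutual-information overlap analysis
    between co-registered functional-activation and electric-field volumes.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
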