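Package: mrcpdecode
Title: Decoding Attempted Hand and Arm Movements from Movement-Related
    Cortical Potentials in EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Simulation and analysis toolkit for decoding attempted arm and
    hand movements from low-frequency electroencephalography (EEG).
    Implements a paradigm-faithful synthetic EEG generator with
    class-dependent movement-related cortical potentials (MRCPs), a
    four-step artifact-removal pipeline (bad-channel detection, Infomax
    ICA with robust sample masking, trial rejection by amplitude, joint
    probability and kurtosis, zero-phase and causal Butterworth
    filtering), shrinkage-regularized linear discriminant analysis with
    softmax probabilities and sliding-window cross-validated accuracy
    curves, difference topoplots with max-statistic permutation testing,
    and an asynchronous (self-paced) movement detection state machine
    with true-positive-window evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ica,
    signal,
    stats,
    utils
Suggests:
    MASS,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
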