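Package: mcdecode
Title: Neuromorphic Motor Control Decoding of ECoG Signals
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A neuromorphic motor control decoder (MCD) for multichannel
    electrocorticographic (ECoG) recordings. Raw signals are turned into
    generating currents by amplitude shifting or squared complex Morlet
    wavelet transforms, injected into a spatially embedded spiking neural
    network of leaky integrate-and-fire neurons with distance-dependent
    small-world connectivity and spike-timing-dependent plasticity, and the
    resulting per-electrode spiking rates are decoded by an Echo State
    Network with online recursive-least-squares readout training and a
    satisfaction-gated reinforcement rule with an eligibility trace.
    Includes a pseudo-online training/decoding pipeline with per-frequency
    model banks and threshold voting, a synthetic ECoG session generator
    with state-dependent spectral structure, EDF and CSV input/output, and
    evaluation metrics (balanced accuracy, F-score, trajectory cosine
    similarity).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
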