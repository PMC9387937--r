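Package: gammastate
Title: Decoding Naturalistic Behavioral States from Intracranial High-Gamma Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for asking whether coarse, naturalistic behavioral states
    (dialogue, electronics use, television, rest) leave discriminable traces in
    the 70-110 Hz band-limited amplitude of intracranial recordings. Implements
    the full analysis chain: signal conditioning of ECoG/sEEG recordings into
    250 ms binned high-gamma envelopes (channel rejection, referencing, notch
    filtering, Hilbert envelope, despiking, per-window z-scoring); 30-second
    epoch features (mean, variance, covariance, slow/fast band-limited power,
    Welch spectra); blocked 7-fold cross-validated decoding with a temporal
    buffer and a binomial finite-sample chance level; and a from-scratch
    Gaussian process factor analysis (GPFA) fit by EM with per-factor timescale
    estimation, orthonormalization, leave-one-channel-out prediction error, and
    a block-structured Gaussian (QDA/LDA) discriminant over latent
    trajectories. A synthetic-data module generates multichannel recordings
    with planted state-dependent statistics so every stage is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    signal,
    e1071,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
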