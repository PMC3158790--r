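Package: ntpsleep
Title: Neuronal Transition Probability Modelling of NREM Sleep EEG Dynamics
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Models the within-episode dynamics of non-REM sleep EEG as a
    two-phase three-mode stochastic cascade: a fixed generating population of
    brainstem neurons whose firing modes (beta, sigma, delta) cascade
    beta-sigma-delta while moving towards deep sleep and delta-sigma-beta while
    moving away, with phase switchovers timed by an external flip-flop.
    Provides closed-form and Monte Carlo simulators of the cascade, a staged
    least-squares fitting procedure mapping band-power time courses to model
    parameters with Fisher-z goodness-of-fit aggregation, spectral
    preprocessing of raw EEG (Hann-windowed FFT band powers, RMS artefact
    masking, hypnogram-based NREM episode segmentation), threshold flip-flop
    crossing detection and event-alignment scoring for paced activity traces,
    cohort-level repeated-measures statistics with polynomial trend contrasts,
    and seeded synthetic-data generators for every input the pipeline consumes.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    jsonlite,
    yaml,
    zoo,
    signal
Suggests:
    testthat (>= 3.0.0),
    deSolve,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
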