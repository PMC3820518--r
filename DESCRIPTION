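Package: mmnsim
Title: Predictive-Coding Simulation of the Auditory Mismatch Negativity
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates the auditory mismatch negativity (MMN) as the scalp
    correlate of precision-weighted prediction errors. A three-level
    hierarchical dynamic model generates loudness-modulated tonotopic
    spectrograms for standard and deviant tones; perception is simulated by
    online generalized (Bayesian) filtering in generalized coordinates of
    motion; the resulting prediction-error trajectories are mapped to a
    single-electrode event-related potential through a sigmoid/lead-field
    forward model with standard ERP post-processing. Includes fractional-area
    latency and windowed-amplitude MMN estimators, multi-start least-squares
    estimation of the observation parameters, and orchestration of deviance
    magnitude by deviant probability oddball experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    signal,
    minpack.lm,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0), optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
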