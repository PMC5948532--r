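Package: myofactors
Title: Synthetic Benchmarking of Surface EMG Interfaces and Their Latent
    Performance Factors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying what limits the performance of surface
    electromyography (sEMG) human-machine interfaces. Provides a synthetic
    generator for multichannel sEMG with latent per-subject factors
    (antagonist co-activation and amplitude attenuation), windowed RMS and
    mean-power feature extraction, a single-hidden-layer neural-network
    gesture classifier with a linear-discriminant baseline, proportional
    cursor control, performance indices (F-measure, mean squared output
    error and its log-median normalisation), ICA-based localisation of
    muscle sources on electrodes with the synergist-antagonist coefficient
    (SAC), and decision-quality analysis of pursuit-game traces (optimal
    interception direction, angular deviation, optimal and incorrect
    gesture rates).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    MASS,
    ica,
    jsonlite,
    signal,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
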