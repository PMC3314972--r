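Package: wcots
Title: Transient Synchronization Modelling of Gamma Activity with Weakly
    Coupled Oscillators
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a dynamical pattern-recognition model of auditory
    cortex in which occurrence-time features extracted from speech-like
    audio drive a network of weakly coupled phase oscillators. Transient
    synchronization of the network signals a recognition event and is used
    as a forward model of high-gamma local field potential activity.
    Provides synthetic word/nonword stimulus generation, FIR filterbank
    and Hilbert-envelope front ends, occurrence-time feature extraction
    with intensity levels and time-warp normalization, spike-rate
    adaptation frequency profiles with plasticity-optimal decay constants,
    Euler-Maruyama integration of the phase dynamics with von Mises noise,
    multitaper log-spectrograms and differential spectrograms,
    Metropolis-Hastings posterior sampling with posterior-harmonic-mean
    evidence, and an isolated-word recognition benchmark comparing
    occurrence-time features against mel-frequency cepstral coefficients
    under additive noise.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
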