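Package: nuws
Title: Analog-to-Feature Conversion Simulator Based on Non-Uniform
    Wavelet Sampling
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulates an analog-to-feature (A2F) converter for low-power
    wireless biomedical sensors. Enumerates Haar, Gabor and constant wavelet
    dictionaries over fixed analysis windows, extracts non-uniform wavelet
    sampling (NUWS) features from windowed multichannel signals, ranks
    candidates by information gain, performs basic, extractor-constrained
    (adapted) and energy-aware (optimized) sequential forward selection
    around a small feedforward neural-network classifier, schedules selected
    features onto parallel hardware extractors, quantizes features to a
    configurable bit depth, and estimates per-feature and whole-chain energy
    consumption for Nyquist, analog-to-information and A2F acquisition
    front-ends. Synthetic ECG-like and inertial-like signal generators make
    the full pipeline testable without external datasets.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    nnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
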