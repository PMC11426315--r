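Package: songsep
Title: Site-Specific Birdsong Source-Separation Datasets and Evaluation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for building supervised source-separation training
    datasets from passive acoustic monitoring of songbirds and for
    evaluating separation quality. Covers detector-score ranking and
    segment extraction, a birdsong cleaning chain (zero-phase Butterworth
    high-pass, peak normalization, stationary spectral gating),
    loudest-five-minutes background mining, a seeded mixture generator with
    time-stretch, pitch-shift and gain augmentation at controlled
    birdsong-background ratios, chunked inference with crossfade merging,
    BSS-eval SDR/SIR/SAR and SI-SDR metrics, Canny-edge minimum/maximum
    frequency labeling, and a time-difference-of-arrival trilateration
    simulator with single-scatter forest impulse responses. Deep separators
    are replaced by a pluggable contract with oracle time-frequency mask
    implementations, so every stage runs at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
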