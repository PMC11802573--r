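Package: neurofuse
Title: Multimodal EEG-EMG Functional-Connectivity Decoding of Movement Intention
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Decodes pre-movement intention (sit-to-stand, stand-to-sit, rest)
    from simultaneous EEG and EMG recordings. Builds functional-connectivity
    adjacency networks per trial window (band-averaged magnitude-squared
    coherence, Pearson correlation, or histogram plug-in mutual information),
    learns discriminative spatial network filters for each class pair by a
    generalized eigendecomposition of class scatter matrices, and classifies by
    pairwise linear support-vector machines with majority voting. Also provides
    Teager-Kaiser energy-operator EMG onset detection, epoching utilities,
    mean/median-frequency muscle-fatigue indices, a seeded synthetic-data
    generator with planted class-dependent cross-channel coupling, and a
    reproducible cross-validation pipeline with binomial chance-level
    thresholds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    e1071,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
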