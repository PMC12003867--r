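Package: swadr
Title: Linking Drug-Induced Gastrointestinal Slow-Wave Changes to Adverse
    Drug Reactions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Simulation and analysis pipeline connecting drug-induced changes
    in gastrointestinal pacemaker (slow-wave) multi-electrode recordings to
    adverse drug reactions (nausea, vomiting, diarrhoea, constipation).
    Provides a synthetic cohort generator for 60-channel microelectrode-array
    recordings, a preprocessing chain (dominant-frequency channel filtering,
    amplitude masking, stability-ranked reference normalization, neighbour
    augmentation, decimation, baseline/post-drug windowing and summated
    interference matrices), SIDER-style adverse-reaction labelling with
    balanced chunking and shuffled-label negative controls, CNN/FCN/
    InceptionTime-style multichannel time-series classifiers with fixed
    tissue and concentration embeddings, a logistic-regression ensemble,
    by-drug aggregation, and time-shifted external validation with the
    accompanying statistical comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    pracma,
    signal,
    stats,
    tools,
    utils,
    yaml,
    zoo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
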