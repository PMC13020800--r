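Package: chronotopo
Title: Duration Population Receptive Fields and Chronotopic Map Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Fits a position-invariant Gaussian duration population receptive
    field (pRF) model to per-vertex condition-wise response amplitudes and
    quantifies the topographic organization of the resulting duration
    preference maps. Provides local and global Moran's I with conditional
    permutation nulls and HH/LL/HL/LH cluster classification, empirical
    variograms with nugget and range extraction, duration-preference
    categorization and occipital-to-frontal gradient regressions, psychometric
    fitting with point-of-subjective-equality (PSE) extraction and its
    rank-correlation link to preferences, Kendall tau correlation matrices
    with complete-linkage dendrograms, and a synthetic-data module that plants
    known tuning fields, forward-simulates response amplitudes, and simulates
    categorization behavior so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
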