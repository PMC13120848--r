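Package: dux4pipe
Title: DUX4 Activity Scoring, siRNA Seed Off-Target Profiling, and Muscle PK/PD Curves
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative pipeline for preclinical evaluation of DUX4-targeting
    siRNA therapeutics in facioscapulohumeral muscular dystrophy (FSHD).
    Implements guide-strand seed extraction and 3'UTR seed-match scanning with a
    simulated-siRNA background, empirical-CDF effect sizes (Mann-Whitney AUC)
    with Kolmogorov-Smirnov tests for seed-based off-target profiling, the
    2^(-ddCt) FSHD composite biomarker score and related qPCR/NanoString
    normalisations, differential-expression signature concordance counting and
    DUX4-responsive panel selection, tissue half-life estimation by ln-linear
    regression, three-parameter log(inhibitor)-response EC50 fitting, Hill
    specific-binding fits, standard-curve quantification, and synthetic-data
    generators emulating each input so the whole pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    minpack.lm,
    jsonlite,
    methods,
    stats,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
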