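Package: icepop
Title: Population Dynamics, Transfer Statistics and Genomic Screening for
    Integrative and Conjugative Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Models and statistics for the bistable transfer-competence
    program of ICEclc-type integrative and conjugative elements. Provides a
    two-subpopulation Monod model of batch and serial-transfer growth with
    stationary-phase switching and transfer-competent cell death (deterministic
    ODE and stochastic agent-based twins), the associated growth statistics
    (ln2/slope generation times, lag times), conjugative transfer frequency and
    survival-rate statistics with pooled-variance t tests and one-way ANOVA
    followed by Tukey-Kramer compact letter displays, single-cell reporter
    fraction calling with Wilson confidence intervals and detection-limit
    accounting, a windowed genomic screen for ICEclc-like elements from
    precomputed homology feature tables, and seeded synthetic-data generators
    for every input the analyses consume.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    deSolve,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    mclust
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
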