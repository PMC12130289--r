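Package: chromspec
Title: Transcription Factor-Nucleosome Competition and Enhancer
    Accessibility Dynamics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Equilibrium modelling of cooperative transcription-factor
    binding in competition with histones at enhancer sites, including a
    mass-conservation solver, binding-specificity landscapes over
    affinity grids, and independent kinetic (ODE and stochastic)
    verification of the equilibrium. Also implements an
    enhancer-dynamics analysis toolkit for CUT&Tag-style data:
    replicate-reproducible peak filtering, active-enhancer definition
    from histone-mark co-occurrence, summit-window fragment counting,
    accessibility-based region classification, rank-sum statistics with
    Bonferroni correction, and transcription-factor co-binding overlap
    summaries, together with a seeded synthetic-data generator so every
    stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    methods,
    S4Vectors,
    IRanges,
    GenomicRanges,
    GenomeInfoDb,
    SummarizedExperiment,
    deSolve,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
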