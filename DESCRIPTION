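Package: SymShuffle
Title: Symbiont Community Shuffling, Diversity and Survival Analysis for
    Coral Early Life Stages
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing Symbiodiniaceae ITS2 amplicon communities in
    coral larvae and juveniles under thermal stress. Implements a hybrid
    taxonomy overlay that collapses amplicon sequence variants (ASVs) into
    defining intragenomic variant (DIV) profiles while retaining rare
    background variants, alpha diversity (Shannon, Pielou evenness) with beta
    regression and pairwise contrasts, Bray-Curtis dissimilarity with
    non-metric multidimensional scaling, PERMANOVA, ANOSIM and multivariate
    dispersion permutation tests, Kaplan-Meier survival estimation with a
    two-group log-rank test, and a Dirichlet-multinomial community and
    interval-monitored survival simulator that emulates the statistical
    structure of heat-stress experiments on vertically transmitting corals.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    jsonlite,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    vegan,
    survival,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
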