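Package: esmscreen
Title: Discovery of Endogenous Sources of Mutation from Tumor Cohorts and
    Fluctuation Assays
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to screen tumor cohorts for endogenous sources of somatic
    mutation (ESMs): construction of 12-channel and complementary-collapsed
    6-channel substitution spectra from somatic SNV catalogs, three
    expression-versus-mutation statistical screens (Spearman correlation,
    burden-group t-test, mutation-status t-test) with candidate selection and
    overlap, transcriptional strand-asymmetry analysis of C>A transversions,
    Kaplan-Meier survival stratification by expression (median and best
    separation), and quantification of Luria-Delbruck rifampicin-resistance
    fluctuation assays including rpoB clone substitution calling and a culture
    simulator. A synthetic-cohort generator with planted effects makes every
    stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    survival,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
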