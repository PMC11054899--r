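Package: platfid
Title: Transcriptional Fidelity Scoring of Tumor Culture Platforms
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantifies how faithfully patient-derived tumor culture platforms
    (liquid-media tumorspheres, collagen and decellularized-matrix scaffolds,
    mouse xenografts) preserve the transcriptional program of the paired
    patient tissue. Selects tumor marker genes by differential expression
    between normal and tumor reference cohorts (pooled-variance t-test with
    Benjamini-Hochberg correction), computes a per-sample platform-versus-
    tissue deviation statistic at the gene, transcription-factor-activity and
    pathway-activity levels (the latter two via a sample-wise kernel-CDF /
    Kolmogorov-Smirnov random-walk enrichment score), clusters samples with
    correlation-distance average linkage, and ranks platforms by similarity
    to tissue. Ships a synthetic-data generator that emulates a paired
    multi-platform study design with planted ground truth, so the whole
    pipeline is testable without external downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    tibble,
    dplyr,
    purrr,
    rlang,
    generics,
    ggplot2,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tidyr,
    ape,
    limma,
    withr
Config/testthat/edition: 3
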