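Package: xenomine
Title: Mining Serial-Passage Xenograft Microarray Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Probe-level preprocessing and mining of human tumor xenograft
    transcriptome cohorts profiled on two-species (human probe, mouse host)
    oligonucleotide arrays. Implements median-intensity scaling, quantile
    normalization and median-polish summarization to log2 expression,
    Present/Marginal/Absent detection calls from an exact Wilcoxon
    signed-rank test on probe-pair discrimination scores, construction and
    application of an empirical mouse cross-hybridization probe-set mask,
    cohort quality control (control-probe profiles, PCA outliers,
    hierarchical co-clustering, an in-silico species-composition score), a
    per-model passage-stability metric, in-vitro to in-vivo transition
    fold-change ranking, EASE-style gene-set over-representation statistics,
    and tumor growth-inhibition (%T/C) efficacy arithmetic. A synthetic-data
    generator with a ground-truth channel makes every stage testable at desk
    scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    limma,
    jsonlite,
    withr
Config/testthat/edition: 3
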