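Package: fflmotif
Title: miRNA-TF-Gene Feed-Forward-Loop Motif Discovery with Survival Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for identifying candidate regulatory driver
    motifs in two-group expression studies (for example tumour versus control
    cohorts in non-small cell lung carcinoma). The pipeline screens genes and
    miRNAs for differential expression with a t-test and a fold-change band
    filter, filters transcription-factor-gene and miRNA-target interaction
    tables by significance, target score and 3'UTR binding, calibrates the
    surviving pairs to the shared miRNAs, assembles a typed tripartite
    regulatory network, enumerates all three-node miRNA feed-forward loops
    (TF activates gene; miRNA represses both), and ranks the loops by the
    summed degree centrality of their members. Companion modules provide
    hypergeometric over-representation analysis of the differential gene list,
    Kaplan-Meier/log-rank survival comparison of median-split expression or
    CpG-methylation groups, and fully seeded synthetic-data generators with
    planted ground truth so every stage is testable without external downloads.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    limma,
    stats,
    survival,
    utils,
    withr,
    yaml
Suggests:
    igraph,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
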