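Package: relqpcr
Title: Relative RT-qPCR Expression Analysis with Replicate Triage and
    Reference-Gene Stability Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A complete workflow for relative quantification of RT-qPCR
    experiments on difficult templates such as FFPE-derived RNA: quality
    triage of technical replicates with configurable Cq-spread thresholds,
    acceptance checks for no-template, no-reverse-transcriptase and internal
    amplification controls, inter-run bridging, reference-gene stability
    ranking by the geNorm, NormFinder, BestKeeper and comparative delta-Cq
    algorithms aggregated into a composite geometric-mean rank, two-reference
    delta-delta-Cq fold changes against a pooled calibrator, nonparametric
    group statistics (tie-corrected Kruskal-Wallis, Mann-Whitney with exact
    and normal-approximation p-values, Benjamini-Hochberg adjustment,
    Spearman correlation), and a seeded cohort simulator with known ground
    truth for end-to-end validation. Ships a worked thymic epithelial tumor
    expression table as a packaged example dataset.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
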