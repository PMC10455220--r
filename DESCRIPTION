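Package: synergyseek
Title: Transcriptional Signatures, Connectivity Scoring and Bliss Synergy
    for Drug-Combination Discovery
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Turns treatment-evoked gene-expression changes in drug-sensitive
    versus drug-resistant leukemia cell lines into ranked, validated
    drug-combination candidates. Implements negative-binomial exact-test
    differential expression with TMM normalization, construction of
    resistance and response expression signatures by cross-cell-line set
    algebra, a Connectivity-Map-style weighted Kolmogorov-Smirnov scoring
    engine (enrichment score, WTCS, normalized connectivity score) with
    candidate filtering and ranking, Bliss-independence synergy scoring of
    dose-response viability matrices with inhibitor-class aggregation, and
    ANOVA association of binary genomic markers with synergy scores using
    Storey-Tibshirani q-values. A synthetic-data module generates inputs
    with planted ground truth so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr,
    optparse
Config/testthat/edition: 3
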