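Package: sigdiscord
Title: Consensus Perturbation Signatures and Disease-Signature Discordance Scoring
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Connectivity-map style drug repositioning toolkit for
    transcriptomic data. Builds a drug's transcriptional consensus response
    signature from multi-cell-line differential z-score profiles, derives
    subgroup-differentiating disease signatures from labeled tumor cohorts,
    scores drug-subgroup discordance by Spearman rank correlation, stratifies
    patients by aggregated gene-set expression into quartiles with log-rank
    survival comparison, ranks signature genes by cell-line dependency scores,
    scores drug-combination surfaces against the highest-single-agent (HSA)
    reference model, and fits four-parameter logistic dose-response and
    one-phase decay curves. Ships seeded synthetic-data generators with
    planted, recoverable ground truth so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    survival,
    minpack.lm,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    mclust,
    optparse,
    yaml
Config/testthat/edition: 3
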