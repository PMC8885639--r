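Package: systeomics
Title: Comparative Multi-Omics Quantification, Enrichment and Membranome Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for comparative "systeomics" analysis of
    proteomes and transcriptomes across cell lines and growth phases.
    Quantifies proteomes by the normalized spectral abundance factor (NSAF)
    and transcriptomes by FPKM and median-of-ratios size factors, integrates
    detection across omics layers, flags differential genes by
    confidence-interval and fold-change rules, tests gene-set (KEGG/GO)
    enrichment and depletion by exact hypergeometric tails with Bonferroni
    adjustment, and classifies proteins as membrane or secreted by consensus
    over subcellular-localization predictor outputs.  A synthetic-data
    generator with planted depleted/enriched terms, planted fold-changes and
    known localization labels supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    pheatmap
Suggests:
    testthat (>= 3.0.0),
    fgsea,
    DESeq2,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
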