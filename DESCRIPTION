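Package: compocor
Title: Composition-Bias-Aware Co-Expression Analysis for RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@compocor.org", role = c("aut", "cre"))
Description: Tools for studying how library-composition bias distorts
    gene-gene correlation estimates in bulk RNA-seq, motivated by the
    mitochondrial transcript fraction problem: when a handful of
    transcripts (for example the 13 mtDNA-encoded OXPHOS genes) dominate
    the read pool, total-count normalizations such as TPM and FPKM couple
    every other gene to the dominant set and induce artefactual
    correlations. The package provides six normalizations implemented
    from their definitions (TPM, FPKM, CPM excluding a gene set, upper
    quartile, median-of-ratios, TMM), per-gene confounder regression, a
    rank-aggregation correlation engine with subsampling, bootstrap and
    random-gene-panel nulls, matched tumour/normal comparison, a
    negative-binomial multi-cohort simulator with planted rank
    correlations and a latent mitochondrial-fraction factor, and
    diagnostics including Hartigan's dip test, composition-bias curves
    and cohort-level meta-correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    Matrix,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    DESeq2,
    edgeR
Config/testthat/edition: 3
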