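Package: troutEpi
Title: Chromatin State, Super-Enhancer, Methylation and Ohnolog Fate
    Analysis for the Rainbow Trout Epigenome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Downstream analysis of functional-epigenome annotations in
    rainbow trout (Oncorhynchus mykiss): base-level fold enrichment of
    chromatin states against genomic elements, tissue-specific gene calling
    from TPM matrices and mark/state specificity contrasts, ROSE-style
    super-enhancer detection from ranked H3K27ac signal, CpG methylation
    depth filtering and meta-profiles around transcription start sites and
    chromatin states, QTL-enhancer-motif intersection with per-chromosome
    enrichment, and classification of the retention fate of
    whole-genome-duplication ohnolog pairs (conserved, neofunctionalized,
    subfunctionalized, specialized) from relative expression profiles with
    promoter epigenetic divergence metrics. A synthetic-data module
    generates every input with planted ground truth so the full pipeline is
    testable at desk scale.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    S4Vectors,
    data.table,
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
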