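Package: multigrn
Title: Cross-Modality TF-Gene Regulatory Network Inference from Paired
    Single-Cell Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Differential motif-activity analysis and cross-modality
    regulatory network inference for paired single-cell RNA and ATAC data.
    Identifies differentially accessible peaks between injury timepoints and
    control (Wilcoxon rank-sum with Benjamini-Hochberg adjustment and
    accessibility-fraction filtering), tests transcription-factor motif
    over-representation in those peaks against a GC-matched background
    (position-weight-matrix scanning and hypergeometric enrichment), links
    transcription-factor expression to target-gene TSS accessibility by
    Spearman correlation to build a TF-gene network, and prioritizes
    candidate regulators consistent across acute and chronic phases. Ships a
    synthetic paired-multiome generator with planted subtypes, condition
    effects, motif placements and TF-target couplings so every stage can be
    validated against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    jsonlite,
    yaml,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
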