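Package: fusionscape
Title: Consensus Calling, Filtering and Landscape Statistics for Expressed Fusion Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Post-processing pipeline for expressed fusion transcripts called
    from bulk RNA-seq by two independent fusion callers. Normalizes the two
    callers' report dialects to a common schema, takes their orientation-aware
    per-sample intersection, applies read-support and gene-family filters,
    scores breakpoint-flank sequence homology with a local-alignment E-score
    to flag alignment artifacts, and computes cohort landscape statistics
    (unique/recurrent/immunoglobulin fusion decomposition, per-sample burden,
    chromosome gene-density correlation) together with permutation tests for
    subgroup comparisons and fused-versus-unfused expression tests. Includes
    a fully synthetic cohort generator (annotation, reference, caller reports,
    metadata, expression) with ground-truth labels for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    rtracklayer,
    jsonlite,
    methods,
    withr,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
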