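Package: genescout
Title: Homology-Guided Discovery of Pathway Genes in Unannotated Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds a user-supplied list of protein-coding genes (for example all
    genes of a pathway) in an unannotated genome assembly. The pipeline seeds
    candidate loci with a translated protein-to-genome similarity search,
    merges and margin-extends high-scoring pairs into strand-specific candidate
    regions, predicts gene structures inside each region with protein hints,
    re-aligns query proteins to the predicted proteins with an ungapped model,
    scores every candidate with a small neural-network filter whose decision
    threshold is calibrated to a target sensitivity, and reduces the scored
    candidates to a final report. Ships a planted-gene genome simulator,
    built-in reference backends for the aligner and gene-predictor stages, and
    an orthology-aware evaluation harness (confusion matrix, coverage, and
    locus categorisation against a truth annotation).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    IRanges,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    rtracklayer,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
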