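Package: florabind
Title: Transcription-Factor Target Discovery from ChIP-Seq and Inducible
    RNA-Seq Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying direct transcription-factor
    target genes by integrating ChIP-Seq binding evidence with an inducible
    time-course differential-expression experiment. Provides threshold-based
    peak calling on tagged-minus-untagged difference coverage tracks,
    positional peak-to-gene annotation against the nearest transcription
    start site, negative-binomial time-course differential expression with
    batch adjustment and Benjamini-Hochberg FDR control, position weight
    matrix scanning with exact dynamic-programming p-values and a
    randomized-peak null, gene-set overlap statistics (hypergeometric tests,
    Jaccard indices, term enrichment), and a synthetic-data generator with
    known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    jsonlite,
    MASS,
    stats,
    utils,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    withr
Config/testthat/edition: 3
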