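Package: nbburden
Title: Non-B DNA Burden Computation and Motif Screening
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Quantifies the prevalence of non-B DNA forming motifs
    (A-phased repeats, G-quadruplexes, Z-DNA, inverted/mirror/direct
    repeats, short tandem repeats) over gene-, signature- and site-level
    genomic queries as a "non-B burden", with raw, per-kilobase,
    per-million and CPKM normalizations. Provides batch burden matrices,
    descriptive gene-screen analytics (totals, composition, interval
    banding, hierarchical burden clustering), k-means screening of motif
    sequence features (length, %G, %A), flank sequence extraction from a
    reference genome, synthetic fixture generators with exact ground
    truth, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    yaml,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
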