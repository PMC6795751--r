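Package: riboloop
Title: Detection of Translated Circular RNAs from Ribosome Profiling Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects translated circular RNAs (circRNAs) from ribosome
    profiling (Ribo-seq) data. Builds a junction-centered pseudo-reference in
    which every candidate circRNA is tandem-duplicated so its back-splice
    junction sits mid-unit, filters and aligns ribosome-protected fragments
    with a gap-free seed-and-verify aligner, extracts junction-covered regions
    supported by more than three junction-spanning reads, classifies them as
    coding or noncoding with a k-mer co-occurrence network feature vector and
    a decision-tree/forest model, and predicts the translated peptide without
    requiring a start codon. Ships a fully seeded synthetic-data generator
    (reads, contaminants, training sets, Markov-chain null sequences) for
    benchmarking and false-discovery-rate estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    igraph,
    purrr,
    randomForest,
    rlang,
    rpart,
    stats,
    stringr,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    BiocGenerics,
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
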