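Package: lncpath
Title: Discovery and Functional Analysis of Plant Long Non-Coding RNAs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A pipeline for identifying long non-coding RNAs (lncRNAs) from
    assembled transcript models and characterising their function, built
    around the biology of allopolyploid plants such as tobacco. Transcripts
    are filtered by length, open reading frame size, protein similarity and
    coding potential, then classified by genomic position into intergenic
    (lincRNA), antisense (NAT) and intronic (incRNA) classes. Downstream
    stages compute TPM expression, tissue specificity, subgenome-of-origin
    calls with a chi-square asymmetry test, microRNA precursor and
    endogenous target mimic (eTM) prediction, cis and trans target
    assignment, weighted co-expression network modules with eigengenes,
    differential expression under an induction contrast, hypergeometric
    enrichment, and extraction of a pathway-focused lncRNA-gene sub-network.
    A fully ground-truthed synthetic data generator makes every stage
    testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    igraph,
    jsonlite,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
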