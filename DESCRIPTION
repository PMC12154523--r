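Package: graftflow
Title: Mobile mRNA Detection and Multi-Omics Integration for Grafted Plants
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Detects graft-transmissible (mobile) mRNAs from RNA-seq of
    heterografted plants by two-stage read classification against the scion
    and rootstock references with an identity threshold and homograft
    false-positive subtraction; quantifies candidate transcripts (FPKM),
    calls differential mobile mRNAs, clusters tissue-specific expression
    profiles by fuzzy c-means, folds candidate transcripts with a
    maximum-pairing model and a partition function to obtain base-pair
    probabilities, positional entropy and a loop census, and integrates
    transcript and metabolite profiles into Spearman correlation networks.
    Ships a fully parameterised synthetic heterograft experiment generator
    with known ground truth so the entire pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings,
    S4Vectors,
    SummarizedExperiment,
    igraph
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
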