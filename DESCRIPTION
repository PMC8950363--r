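Package: igloci
Title: Annotation and Characterization of Immunoglobulin Germline Loci
Version: 1.0.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Tools for curating immunoglobulin (IG) heavy and light chain
    germline loci: coordinate arithmetic and assembly-gap detection on locus
    sequences, clustering of V genes into subgroups by nucleotide identity,
    IMGT-style gene and allele nomenclature, allele matching against a
    reference directory, functionality calls (functional, ORF, pseudogene),
    template-based placement of V domains on the IMGT unique-numbering grid
    with CDR length triplets and protein displays, extraction of V(D)J
    recombination signals with consensus and canonicality rules, scanning of
    5' UTR promoter elements (octamer, decamer, TATA box, E-box and friends),
    simulation of synthetic loci with fully known ground truth, and
    aggregation into repertoire summary tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    igraph,
    IRanges,
    GenomicRanges,
    purrr,
    readr,
    rlang,
    rtracklayer,
    S4Vectors,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    jsonlite,
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
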