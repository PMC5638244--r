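Package: genomesurvey
Title: Genome Survey Statistics for Highly Heterozygous Marine Invertebrate Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Toolkit for the computational survey of a highly heterozygous
    animal genome: canonical k-mer spectrum construction with peak detection
    and spectral genome-size estimation; heterozygosity estimated three ways
    (simulated-spectrum matching, the KHR/BHR k-mer formulas, and
    mapping-variant counting); assembly continuity and completeness
    arithmetic (Nx statistics, printed-ratio reproduction, the Kosambi map
    function, gene-model filtering); detection of tandem-duplicated gene
    clusters and proximity clusters; a nine-stage regeneration expression
    screen with FPKM conversion, housekeeping normalisation, fold-change
    screening and average-linkage profile clustering; and codon-usage bias
    statistics (RSCU, CAI, effective number of codons, correspondence
    analysis). Every input can be produced by the built-in synthetic-data
    generators with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    readr,
    rlang,
    generics,
    ggplot2,
    jsonlite,
    withr,
    stats,
    utils,
    Biostrings,
    GenomicRanges,
    IRanges,
    rtracklayer,
    S4Vectors
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
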