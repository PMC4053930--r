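Package: hetasm
Title: Heterozygosity-Aware De Novo Assembly and Variant-Density Toolkit
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A desk-scale toolkit for assembling highly heterozygous diploid
    genomes and locating hemizygous (sex-linked) sequence. Implements a de
    Bruijn graph assembler with heterozygosity bubble popping (short
    two-SNV rule, long 90 percent-identity rule, and scaffolding across
    complex bubbles with N spans sized by the longest interior path),
    orientation filtering of chimeric mate-pair reads, contig scaffolding
    under minimum contig-size (s) and minimum link-support (n) thresholds,
    transcript-evidence scaffold merging, per-scaffold SNV-density
    classification of hemizygous candidate scaffolds, and pooled-population
    SNP calling with coverage, count, frequency and neighbourhood-quality
    filters. A built-in diploid genome and read simulator with truth tables
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    generics,
    ggplot2,
    jsonlite,
    yaml,
    stats,
    utils,
    Biostrings,
    S4Vectors,
    GenomicRanges,
    IRanges,
    rtracklayer
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
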