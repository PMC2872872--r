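Package: repeatsurveyr
Title: Repeat Discovery and Quantification from Low-Coverage Genome Survey Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for sub-1x shotgun genome surveys of large,
    repeat-rich plant genomes. Simulates 454-style survey reads and small-RNA
    signatures over synthetic genomes with planted repeat families, discovers
    repeat families de novo by non-cognate assembly (exact-overlap read
    clustering with Lander-Waterman significance), estimates genomic copy
    number and genome fraction from alignment depth, quantifies small-RNA
    production per repeat family with copy-number binning and linearity
    statistics, and classifies ribosomal DNA reads to parental ITS2
    haplotypes in interspecific hybrids. Includes a seed-and-extend local
    aligner, genome-size and gene-space arithmetic for survey data, and
    readers/writers for FASTA, FASTQ, tabular alignments and NEXUS.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    Biostrings,
    IRanges,
    S4Vectors,
    igraph,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml,
    jsonlite,
    knitr,
    rmarkdown
Config/testthat/edition: 3
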