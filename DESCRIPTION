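Package: mutcand
Title: Candidate-Gene Discovery from Irradiated-Mutant Multi-Omics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested pipeline for identifying candidate genes behind
    radiation-induced mutant phenotypes from whole-genome resequencing and
    bulk RNA-seq of a wild type and mutant siblings. Covers GATK-style hard
    filtering and normalization of variant call sets, subtraction of
    mutant-private ("induced") SNPs and indels, genomic-element
    classification and functional-consequence annotation
    (splice-site, start/stop codon, frameshift, missense), observed/expected
    element enrichment against random control sites, windowed variant
    density and a log10 depth-of-coverage ratio screen for large structural
    variants, negative-binomial differential expression with
    Benjamini-Hochberg control, and the final intersection of shared
    differentially expressed genes with shared large-effect-variant genes.
    Ships a synthetic-data module that generates genomes, gene models,
    variant trios, coverage tracks and count matrices with planted ground
    truth so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb,
    rtracklayer,
    vcfR,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    knitr,
    rmarkdown
Config/testthat/edition: 3
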