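Package: bsamapr
Title: Bulked-Segregant Association Mapping from Pooled Sequencing
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Maps trait loci from bulked-segregant sequencing of an F2
    population. Reads multi-sample VCFs with per-sample allele depths,
    applies high-quality SNP filters (biallelic, per-sample depth,
    between-pool genotype difference, parental-origin consistency),
    annotates SNP locations against gene models, and runs two genome
    scans: a Euclidean-distance statistic on pooled nucleotide
    frequencies with loess smoothing and a median-plus-3-SD threshold,
    and a delta SNP-index sliding-window scan with Monte-Carlo
    confidence bounds. Candidate regions from the two scans are
    intersected and summarized (interval size, gene count, SNP count).
    Includes a fully seeded F2 bulk-sequencing simulator (Haldane
    recombination, incompletely dominant causal locus, tail-selected
    bulks, pooled read sampling) and a pH-differential anthocyanin
    assay calculator used to phenotype simulated extracts.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    GenomicRanges,
    IRanges,
    jsonlite,
    rtracklayer,
    S4Vectors,
    stats,
    tibble,
    utils,
    vcfR
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
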