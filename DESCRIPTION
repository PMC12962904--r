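Package: bsascan
Title: Bulked Segregant Analysis QTL Mapping from Pooled Sequencing
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: QTL-seq style bulked segregant analysis (BSA) of an F2
    population from pooled whole-genome resequencing of two parents and
    two extreme-phenotype bulks. Reads pooled variant calls (VCF with
    per-sample allele depths), applies hard site-quality filters and a
    parent-informativeness selection, computes per-site SNP-index,
    delta-SNP-index and the fourth power of the Euclidean distance (ED^4)
    between bulk allele-frequency vectors, aggregates them into sliding
    window and LOESS-smoothed genome scans with simulation-based and
    top-percentile significance thresholds, calls per-method candidate
    intervals and their consensus QTL, and annotates candidate SNPs
    against gene models (coding effects from GFF3 plus genome FASTA).
    A complete synthetic F2 pooled-sequencing generator (Haldane meiosis,
    incompletely dominant single locus, extreme bulk selection, binomial
    read sampling) provides ground truth for end-to-end verification.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    grDevices,
    vcfR,
    IRanges,
    GenomicRanges,
    S4Vectors,
    Biostrings,
    rtracklayer,
    ggplot2,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
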