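# random protein-coding gene written as GFF3 + FASTA; optionally mirrored
# (reverse-complemented genome with flipped coordinates and strand)
random_gene_files <- function(seed, mirror = FALSE) {
  set.seed(seed)
  n <- 3000
  seq <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  strand <- sample(c("+", "-"), 1)
  two_seg <- runif(1) < 0.5
  if (two_seg) {
    cds <- rbind(c(901, 990), c(1101, 1190))        # 90 + 90 = 180
  } else {
    cds <- rbind(c(901, 1080))                       # 180
  }
  gene_span <- c(801, 1290)
  if (mirror) {
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    seq <- rev(unname(comp[seq]))
    flip <- function(se) sort(c(n - se[2] + 1, n - se[1] + 1))
    cds <- t(apply(cds, 1, flip))
    cds <- cds[order(cds[, 1]), , drop = FALSE]
    gene_span <- sort(n - gene_span + 1)
    strand <- if (strand == "+") "-" else "+"
  }
  gff <- c("##gff-version 3",
           sprintf("chrR\tt\tgene\t%d\t%d\t.\t%s\t.\tID=g1", gene_span[1],
                   gene_span[2], strand),
           sprintf("chrR\tt\tmRNA\t%d\t%d\t.\t%s\t.\tID=g1.t;Parent=g1",
                   gene_span[1], gene_span[2], strand),
           sprintf("chrR\tt\texon\t%d\t%d\t.\t%s\t.\tParent=g1.t",
                   cds[, 1], cds[, 2], strand),
           sprintf("chrR\tt\tCDS\t%d\t%d\t.\t%s\t0\tParent=g1.t",
                   cds[, 1], cds[, 2], strand))
  dir <- tempfile("rg_"); dir.create(dir)
  gff3 <- file.path(dir, "g.gff3"); fasta <- file.path(dir, "g.fa")
  writeLines(gff, gff3)
  writeLines(c(">chrR", paste(seq, collapse = "")), fasta)
  list(gff3 = gff3, fasta = fasta, seq = seq, cds = cds, strand = strand,
       n = n)
}

# oracle: translate the whole CDS before and after the substitution
translate_diff_oracle <- function(seq, cds, strand, pos, alt) {
  splice <- function(s) {
    paste(unlist(lapply(seq_len(nrow(cds)), function(i)
      s[cds[i, 1]:cds[i, 2]])), collapse = "")
  }
  mut <- seq; mut[pos] <- alt
  to_aa <- function(x) {
    d <- Biostrings::DNAString(x)
    if (strand == "-") d <- Biostrings::reverseComplement(d)
    as.character(Biostrings::translate(d, if.fuzzy.codon = "X"))
  }
  aa_ref <- to_aa(splice(seq)); aa_alt <- to_aa(splice(mut))
  diff <- which(strsplit(aa_ref, "")[[1]] != strsplit(aa_alt, "")[[1]])
  if (!length(diff))
    list(category = "EXON:SYNONYMOUS_CODING", aa_change = NA)
  else
    list(category = "EXON:NON_SYNONYMOUS_CODING",
         aa_change = paste0(substr(aa_ref, diff, diff), diff,
                            substr(aa_alt, diff, diff)))
}

test_that("gene models load with canonical transcripts and validation", {
  fx <- make_gene_fixture()
  models <- suppressMessages(load_gene_models(fx$gff3, fx$fasta))
  expect_setequal(models$genes$gene_id, c("geneP", "geneM"))
  expect_true("geneBad" %in% models$skipped)      # CDS length 100 not %% 3
  expect_equal(length(models$exons[["geneP"]]), 2L)
  # minus-strand exons stored ascending with the strand flag set
  expect_equal(models$genes$strand[models$genes$gene_id == "geneM"], "-")
  expect_true(all(diff(IRanges::start(models$exons[["geneM"]])) > 0))
  expect_equal(models$genes$description[models$genes$gene_id == "geneP"],
               "plus gene")
  # FASTA must cover every GFF3 chromosome
  bad_fa <- tempfile(fileext = ".fa")
  writeLines(c(">other", "ACGT"), bad_fa)
  expect_error(load_gene_models(fx$gff3, bad_fa), "absent from FASTA")
})

test_that("location classification covers every category", {
  fx <- make_gene_fixture()
  models <- suppressMessages(load_gene_models(fx$gff3, fx$fasta))
  at <- function(pos, ref = substr(fx$seq, pos, pos), alt = "A") {
    if (alt == ref) alt <- "C"
    make_variant(chrom = "chrT", pos = pos, ref = ref, alt = alt)
  }
  cls <- function(pos) classify_variant_location(at(pos), models)$category
  expect_equal(cls(1150), "INTRON")          # between geneP exons
  expect_equal(cls(1020), "UTR_5_PRIME")     # exonic before + strand CDS
  expect_equal(cls(1310), "UTR_3_PRIME")     # exonic after + strand CDS
  expect_equal(cls(201), "UPSTREAM")         # 800 bp 5' of the + strand TSS
  expect_equal(cls(1430), "DOWNSTREAM")
  expect_equal(cls(10000), "INTERGENIC")     # > 5 kb from any gene
  # minus-strand gene: orientation flips
  expect_equal(cls(20450), "UPSTREAM")
  expect_equal(cls(19990), "DOWNSTREAM")
  expect_equal(cls(20360), "UTR_5_PRIME")
  expect_equal(cls(20020), "UTR_3_PRIME")
  expect_equal(cls(20200), "INTRON")
  # classification partitions: exactly one category per SNP
  pos_all <- c(1150, 1020, 1310, 201, 1430, 10000, 20450, 19990, 20360,
               20020, 20200, 1053)
  res <- classify_variant_location(
    do.call(rbind, lapply(pos_all, at)), models)
  expect_equal(nrow(res), length(pos_all))
  expect_true(all(res$category %in% c(
    "EXON:SYNONYMOUS_CODING", "EXON:NON_SYNONYMOUS_CODING", "UTR_5_PRIME",
    "UTR_3_PRIME", "INTRON", "UPSTREAM", "DOWNSTREAM", "INTERGENIC")))
})

test_that("coding effects translate planted codons correctly", {
  fx <- make_gene_fixture()
  models <- suppressMessages(load_gene_models(fx$gff3, fx$fasta))
  # codon 1 is planted ATG; G>A at its third base gives Met -> Ile
  eff <- coding_effect(list(chrom = "chrT", pos = 1053, ref = "G",
                            alt = "A"), "geneP", models)
  expect_equal(eff$category, "EXON:NON_SYNONYMOUS_CODING")
  expect_equal(eff$aa_change, "M1I")
  # codon 2 is planted GCT; T>C gives Ala -> Ala (synonymous)
  eff2 <- coding_effect(list(chrom = "chrT", pos = 1056, ref = "T",
                             alt = "C"), "geneP", models)
  expect_equal(eff2$category, "EXON:SYNONYMOUS_CODING")
  expect_equal(eff2$aa_change, "A2A")
  # REF disagreeing with the genome names the site
  expect_error(coding_effect(list(chrom = "chrT", pos = 1053, ref = "C",
                                  alt = "A"), "geneP", models),
               "REF mismatch at chrT:1053")
})

test_that("coding effects agree with a translate-and-diff oracle", {
  for (seed in 1:50) {
    fx <- random_gene_files(seed)
    models <- load_gene_models(fx$gff3, fx$fasta)
    cds_pos <- unlist(apply(fx$cds, 1, function(r) r[1]:r[2]))
    pos <- sample(cds_pos, 1)
    ref <- fx$seq[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    eff <- coding_effect(list(chrom = "chrR", pos = pos, ref = ref,
                              alt = alt), "g1", models)
    oracle <- translate_diff_oracle(fx$seq, fx$cds, fx$strand, pos, alt)
    expect_equal(eff$category, oracle$category)
    if (!is.na(oracle$aa_change))
      expect_equal(eff$aa_change, oracle$aa_change)
  }
})

test_that("mirroring the genome leaves effects invariant", {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (seed in 51:62) {
    fx <- random_gene_files(seed)
    mx <- random_gene_files(seed, mirror = TRUE)
    m1 <- load_gene_models(fx$gff3, fx$fasta)
    m2 <- load_gene_models(mx$gff3, mx$fasta)
    cds_pos <- unlist(apply(fx$cds, 1, function(r) r[1]:r[2]))
    set.seed(seed + 1000)
    for (pos in sample(cds_pos, 5)) {
      ref <- fx$seq[pos]
      alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
      e1 <- coding_effect(list(chrom = "chrR", pos = pos, ref = ref,
                               alt = alt), "g1", m1)
      e2 <- coding_effect(list(chrom = "chrR", pos = fx$n - pos + 1,
                               ref = comp[[ref]], alt = comp[[alt]]),
                          "g1", m2)
      expect_equal(e1$category, e2$category)
      expect_equal(e1$aa_change, e2$aa_change)
    }
  }
})

test_that("candidate table is interval-restricted and sorted", {
  stats <- data.frame(
    chrom = "chr10", pos = c(100, 200, 300, 400, 5000),
    delta_snp_index = c(0.5, 0.9, 0.9, -0.95, 1.0),
    ed4 = c(0.2, 3.0, 3.5, 3.2, 4.0))
  effects <- data.frame(
    chrom = "chr10", pos = stats$pos, ref = "A", alt = "G",
    gene_id = paste0("g", 1:5), category = "INTRON",
    aa_change = NA_character_, description = NA_character_)
  interval <- data.frame(chrom = "chr10", start = 150, end = 450)
  tab <- build_candidate_table(effects, stats, interval)
  expect_equal(nrow(tab), 3L)                 # 100 and 5000 excluded
  # |delta| descending, ED^4 breaking the 0.9 tie
  expect_equal(tab$pos, c(400, 300, 200))
  expect_equal(tab$gene_id, c("g4", "g3", "g2"))
})
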