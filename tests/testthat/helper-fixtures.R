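# Fixture builders shared across the suite. Everything is generated in code;
# files go to tempdir().

# one pooled-variant row with clean pass-filter QC; override any field
make_variant <- function(chrom = "chr01", pos = 100, ref = "A", alt = "G",
                         dp = 180, qual = 900, mq = 60, qd = 25, fs = 1,
                         an = 8, sor = 1,
                         parent_purple = c(0, 45), parent_green = c(45, 0),
                         bulk_purple = c(5, 40), bulk_green = c(40, 5)) {
  row <- data.frame(chrom = chrom, pos = pos, ref = ref, alt = alt,
                    dp = dp, qual = qual, mq = mq, qd = qd, fs = fs,
                    an = an, sor = sor, stringsAsFactors = FALSE)
  pools <- list(parent_purple = parent_purple, parent_green = parent_green,
                bulk_purple = bulk_purple, bulk_green = bulk_green)
  for (role in names(pools)) {
    row[[paste0(role, "_ref")]] <- pools[[role]][1]
    row[[paste0(role, "_alt")]] <- pools[[role]][2]
  }
  row
}

make_variants <- function(...) {
  rows <- list(...)
  do.call(rbind, rows)
}

# hand-written VCF text with arbitrary records (for indel/multiallelic cases)
write_toy_vcf <- function(records, path,
                          samples = c("EP02", "EP01", "ZS", "LS")) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"m\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"q\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"f\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"a\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"s\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"ad\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}

toy_vcf_record <- function(chrom = "chr01", pos, ref = "A", alt = "G",
                           qual = 900,
                           info = "DP=180;MQ=60;QD=25;FS=1;AN=8;SOR=5",
                           ads = c("0,45", "45,0", "5,40", "40,5")) {
  paste(c(chrom, pos, ".", ref, alt, qual, "PASS", info, "AD", ads),
        collapse = "\t")
}

# a two-gene annotation fixture: plus- and minus-strand genes with
# two CDS exons each, written as GFF3 + FASTA in tempdir()
make_gene_fixture <- function(dir = tempfile("genes_")) {
  dir.create(dir, showWarnings = FALSE)
  set.seed(42)
  n <- 30000
  seq <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
  # plus-strand gene: exon1 1001-1100 (UTR5 1001-1050, CDS 1051-1100),
  # intron, exon2 1201-1330 (CDS 1201-1300, UTR3 1301-1330); CDS len 150
  substr(seq, 1051, 1056) <- "ATGGCT"
  gff <- c(
    "##gff-version 3",
    "chrT\ttest\tgene\t1001\t1330\t.\t+\t.\tID=geneP;description=plus gene",
    "chrT\ttest\tmRNA\t1001\t1330\t.\t+\t.\tID=geneP.t1;Parent=geneP",
    "chrT\ttest\texon\t1001\t1100\t.\t+\t.\tID=geneP.e1;Parent=geneP.t1",
    "chrT\ttest\texon\t1201\t1330\t.\t+\t.\tID=geneP.e2;Parent=geneP.t1",
    "chrT\ttest\tCDS\t1051\t1100\t.\t+\t0\tID=geneP.c1;Parent=geneP.t1",
    "chrT\ttest\tCDS\t1201\t1300\t.\t+\t2\tID=geneP.c2;Parent=geneP.t1",
    # minus-strand gene: span 20001-20400; exons 20001-20150 and
    # 20251-20400; CDS 20051-20150 + 20251-20351 (201 bp total)
    "chrT\ttest\tgene\t20001\t20400\t.\t-\t.\tID=geneM;description=minus gene",
    "chrT\ttest\tmRNA\t20001\t20400\t.\t-\t.\tID=geneM.t1;Parent=geneM",
    "chrT\ttest\texon\t20001\t20150\t.\t-\t.\tID=geneM.e1;Parent=geneM.t1",
    "chrT\ttest\texon\t20251\t20400\t.\t-\t.\tID=geneM.e2;Parent=geneM.t1",
    "chrT\ttest\tCDS\t20051\t20150\t.\t-\t0\tID=geneM.c1;Parent=geneM.t1",
    "chrT\ttest\tCDS\t20251\t20351\t.\t-\t0\tID=geneM.c2;Parent=geneM.t1",
    # malformed gene: CDS length 100, not divisible by 3
    "chrT\ttest\tgene\t25001\t25200\t.\t+\t.\tID=geneBad",
    "chrT\ttest\tmRNA\t25001\t25200\t.\t+\t.\tID=geneBad.t1;Parent=geneBad",
    "chrT\ttest\texon\t25001\t25200\t.\t+\t.\tParent=geneBad.t1",
    "chrT\ttest\tCDS\t25001\t25100\t.\t+\t0\tParent=geneBad.t1")
  gff_path <- file.path(dir, "genes.gff3")
  fa_path <- file.path(dir, "genome.fa")
  writeLines(gff, gff_path)
  writeLines(c(">chrT", seq), fa_path)
  list(gff3 = gff_path, fasta = fa_path, seq = seq, dir = dir)
}

# scaled-down end-to-end experiment used by the recovery/specificity checks
run_scaled_experiment <- function(seed, no_qtl = FALSE) {
  sim <- simulate_bsa_experiment(seed = seed, no_qtl = no_qtl)
  filt <- apply_quality_filters(sim$variants)
  info <- select_informative_snps(filt$retained)
  sites <- site_stats(info)
  scan <- genome_scan(sites, seed = seed)
  iv_d <- call_intervals(scan$windows, "delta_sig", sites = scan$sites,
                         site_stat = "delta_snp_index",
                         site_threshold = scan$delta_site_threshold,
                         method = "delta")
  iv_e <- call_intervals(scan$windows, "ed4_sig", sites = scan$sites,
                         site_stat = "ed4",
                         site_threshold = scan$ed4_threshold,
                         method = "ed4")
  list(consensus = intersect_interval_sets(iv_d, iv_e),
       truth = sim$truth, scan = scan)
}
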