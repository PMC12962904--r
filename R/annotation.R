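#' Load gene models from GFF3 and genome FASTA
#'
#' Imports gene/mRNA/exon/CDS features (via rtracklayer) and the genome
#' sequence (via Biostrings), keeping one canonical transcript per gene --
#' the one with the longest total CDS. Genes failing validation (exons
#' outside the gene span, CDS outside exons, CDS length not divisible by 3,
#' or no CDS at all) are skipped and logged.
#'
#' @param gff3 path to a GFF3 file.
#' @param fasta path to the genome FASTA (all GFF3 chromosomes must be
#'   present, else an error).
#' @return a `gene_models` list: `genes` (data.frame with `gene_id`,
#'   `chrom`, `strand`, `start`, `end`, `description`), `exons` and `cds`
#'   (per-gene lists of ascending-sorted IRanges), `genome`
#'   (a `DNAStringSet`), and attribute `skipped` naming dropped genes.
#' @export
load_gene_models <- function(gff3, fasta) {
  gr <- rtracklayer::import(gff3, format = "gff3")
  genome <- Biostrings::readDNAStringSet(fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))
  chroms <- unique(as.character(GenomicRanges::seqnames(gr)))
  missing <- setdiff(chroms, names(genome))
  if (length(missing))
    stop("chromosomes in GFF3 absent from FASTA: ",
         paste(missing, collapse = ", "))

  typ <- as.character(gr$type)
  ids <- as.character(gr$ID)
  parents <- vapply(as.list(gr$Parent), function(p)
    if (length(p)) p[[1]] else NA_character_, "")

  gene_idx <- which(typ == "gene")
  tx_idx <- which(typ %in% c("mRNA", "transcript"))
  feature_ranges <- function(kind, parent_id) {
    sel <- which(typ == kind & parents == parent_id)
    if (!length(sel)) return(IRanges::IRanges())
    r <- IRanges::IRanges(GenomicRanges::start(gr)[sel],
                          GenomicRanges::end(gr)[sel])
    r[order(IRanges::start(r))]
  }

  rows <- list(); exons <- list(); cds <- list(); skipped <- character(0)
  for (gi in gene_idx) {
    gid <- ids[gi]
    tx <- ids[tx_idx][parents[tx_idx] == gid]
    if (!length(tx)) tx <- gid  # exon/CDS parented directly on the gene
    cds_by_tx <- lapply(tx, feature_ranges, kind = "CDS")
    cds_len <- vapply(cds_by_tx, function(r) sum(IRanges::width(r)), 0)
    if (all(cds_len == 0)) { skipped <- c(skipped, gid); next }
    best <- which.max(cds_len)
    ex <- feature_ranges("exon", tx[best])
    cd <- cds_by_tx[[best]]
    if (!length(ex)) ex <- cd
    g_start <- GenomicRanges::start(gr)[gi]; g_end <- GenomicRanges::end(gr)[gi]
    ok <- all(IRanges::start(ex) >= g_start & IRanges::end(ex) <= g_end) &&
      sum(IRanges::width(cd)) %% 3 == 0 &&
      all(IRanges::overlapsAny(cd, ex, type = "within"))
    if (!ok) { skipped <- c(skipped, gid); next }
    desc <- NA_character_
    for (f in c("description", "Note", "product"))
      if (f %in% names(S4Vectors::mcols(gr)) &&
          !is.na(d <- as.character(unlist(S4Vectors::mcols(gr)[[f]][gi])[1])))
        { desc <- d; break }
    rows[[gid]] <- data.frame(
      gene_id = gid, chrom = as.character(GenomicRanges::seqnames(gr))[gi],
      strand = as.character(GenomicRanges::strand(gr))[gi],
      start = g_start, end = g_end, description = desc,
      stringsAsFactors = FALSE)
    exons[[gid]] <- ex
    cds[[gid]] <- cd
  }
  if (length(skipped))
    message("load_gene_models: skipped malformed genes: ",
            paste(skipped, collapse = ", "))
  genes <- if (length(rows)) do.call(rbind, rows) else
    data.frame(gene_id = character(0), chrom = character(0),
               strand = character(0), start = numeric(0), end = numeric(0),
               description = character(0))
  rownames(genes) <- NULL
  structure(list(genes = genes, exons = exons, cds = cds, genome = genome,
                 skipped = skipped),
            class = "gene_models")
}

EFFECT_SEVERITY <- c("EXON:NON_SYNONYMOUS_CODING" = 1,
                     "EXON:SYNONYMOUS_CODING" = 2,
                     "UTR_5_PRIME" = 3, "UTR_3_PRIME" = 3,
                     "INTRON" = 4,
                     "UPSTREAM" = 5, "DOWNSTREAM" = 5,
                     "INTERGENIC" = 6)

#' Coding effect of a SNP inside a CDS
#'
#' Builds the reference codon strand-aware (frame from the canonical CDS),
#' substitutes the ALT base (reverse-complemented for minus-strand genes),
#' and translates both with the standard nuclear genetic code.
#'
#' @param variant one-row data.frame (or list) with `chrom`, `pos`, `ref`,
#'   `alt`.
#' @param gene_id gene identifier in `models`.
#' @param models a `gene_models` object.
#' @return list with `category` (`"EXON:SYNONYMOUS_CODING"` or
#'   `"EXON:NON_SYNONYMOUS_CODING"`) and `aa_change` (e.g. `"M1I"`,
#'   one-letter refAA / codon number / altAA).
#' @export
coding_effect <- function(variant, gene_id, models) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  cd <- models$cds[[gene_id]]
  pos <- variant$pos
  seg <- which(IRanges::start(cd) <= pos & IRanges::end(cd) >= pos)
  if (!length(seg)) stop("variant not inside the CDS of ", gene_id)
  chrom_seq <- models$genome[[g$chrom]]
  cds_seq <- do.call(Biostrings::xscat, lapply(seq_along(cd), function(i)
    Biostrings::subseq(chrom_seq, IRanges::start(cd)[i], IRanges::end(cd)[i])))
  if (g$strand == "-") cds_seq <- Biostrings::reverseComplement(cds_seq)
  w <- IRanges::width(cd)
  if (g$strand == "+") {
    cds_pos <- sum(w[seq_len(seg - 1)]) + (pos - IRanges::start(cd)[seg] + 1)
  } else {
    cds_pos <- sum(w[-seq_len(seg)]) + (IRanges::end(cd)[seg] - pos + 1)
  }
  base_at <- as.character(Biostrings::subseq(cds_seq, cds_pos, cds_pos))
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  ref_cds <- if (g$strand == "+") variant$ref else comp[[variant$ref]]
  alt_cds <- if (g$strand == "+") variant$alt else comp[[variant$alt]]
  genome_ref <- if (g$strand == "+") base_at else comp[[base_at]]
  if (genome_ref != variant$ref)
    stop(sprintf("REF mismatch at %s:%d: VCF %s vs genome %s",
                 g$chrom, as.integer(pos), variant$ref, genome_ref))
  codon_i <- ceiling(cds_pos / 3)
  codon <- as.character(
    Biostrings::subseq(cds_seq, 3 * codon_i - 2, 3 * codon_i))
  offset <- cds_pos - 3 * (codon_i - 1)
  codon_alt <- codon
  substr(codon_alt, offset, offset) <- alt_cds
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[codon_alt]]
  list(category = if (aa_ref == aa_alt) "EXON:SYNONYMOUS_CODING"
       else "EXON:NON_SYNONYMOUS_CODING",
       aa_change = paste0(aa_ref, codon_i, aa_alt))
}

# internal: classify one variant against one gene
classify_against_gene <- function(variant, gene_id, models, flank) {
  g <- models$genes[models$genes$gene_id == gene_id, ]
  pos <- variant$pos
  if (pos >= g$start && pos <= g$end) {
    cd <- models$cds[[gene_id]]
    ex <- models$exons[[gene_id]]
    in_cds <- any(IRanges::start(cd) <= pos & IRanges::end(cd) >= pos)
    if (in_cds) {
      eff <- coding_effect(variant, gene_id, models)
      return(list(category = eff$category, aa_change = eff$aa_change))
    }
    in_exon <- any(IRanges::start(ex) <= pos & IRanges::end(ex) >= pos)
    if (in_exon) {
      before_cds <- pos < min(IRanges::start(cd))
      utr5 <- if (g$strand == "+") before_cds else pos > max(IRanges::end(cd))
      return(list(category = if (utr5) "UTR_5_PRIME" else "UTR_3_PRIME",
                  aa_change = NA_character_))
    }
    return(list(category = "INTRON", aa_change = NA_character_))
  }
  before <- pos < g$start
  upstream <- if (g$strand == "+") before else !before
  list(category = if (upstream) "UPSTREAM" else "DOWNSTREAM",
       aa_change = NA_character_)
}

#' Classify variant genomic context against gene models
#'
#' Each SNP receives exactly one category: inside a gene it is
#' `EXON:SYNONYMOUS_CODING` / `EXON:NON_SYNONYMOUS_CODING` (within CDS, via
#' [coding_effect()]), `UTR_5_PRIME` / `UTR_3_PRIME` (exonic outside CDS,
#' strand-aware), or `INTRON`; within `flank` bp of a gene it is `UPSTREAM`
#' or `DOWNSTREAM` (strand-aware); otherwise `INTERGENIC`. A SNP hitting
#' several genes keeps the most severe category (coding > UTR > intron >
#' up/downstream), with the nearest gene breaking ties.
#'
#' @param variants pooled variant data.frame (needs `chrom`, `pos`, `ref`,
#'   `alt`).
#' @param models a `gene_models` object from [load_gene_models()].
#' @param flank distance in bp defining UPSTREAM/DOWNSTREAM (default 5000).
#' @return data.frame with `chrom`, `pos`, `ref`, `alt`, `gene_id`,
#'   `category`, `aa_change`, `description`.
#' @export
classify_variant_location <- function(variants, models, flank = 5000) {
  genes <- models$genes
  n <- nrow(variants)
  out <- data.frame(chrom = variants$chrom, pos = variants$pos,
                    ref = variants$ref, alt = variants$alt,
                    gene_id = NA_character_, category = "INTERGENIC",
                    aa_change = NA_character_,
                    description = NA_character_,
                    stringsAsFactors = FALSE)
  if (!nrow(genes)) return(out)
  for (i in seq_len(n)) {
    pos <- variants$pos[i]
    cand <- which(genes$chrom == variants$chrom[i] &
                    genes$start - flank <= pos & genes$end + flank >= pos)
    if (!length(cand)) next
    best <- NULL; best_rank <- Inf; best_dist <- Inf
    for (j in cand) {
      cl <- classify_against_gene(variants[i, ], genes$gene_id[j], models,
                                  flank)
      rank <- EFFECT_SEVERITY[[cl$category]]
      dist <- max(0, genes$start[j] - pos, pos - genes$end[j])
      if (rank < best_rank || (rank == best_rank && dist < best_dist)) {
        best <- c(cl, gene_id = genes$gene_id[j],
                  description = genes$description[j])
        best_rank <- rank; best_dist <- dist
      }
    }
    out$gene_id[i] <- best$gene_id
    out$category[i] <- best$category
    out$aa_change[i] <- best$aa_change
    out$description[i] <- best$description
  }
  out
}

#' Build the candidate-SNP report table
#'
#' Restricts annotated SNPs to the consensus QTL interval and orders them by
#' descending |delta-SNP-index|, ties broken by descending ED^4 -- the
#' strongest-association-first layout of a candidate table.
#'
#' @param effects output of [classify_variant_location()].
#' @param stats output of [site_stats()] (same coordinates).
#' @param interval one or more consensus intervals (data.frame with `chrom`,
#'   `start`, `end`).
#' @return data.frame with `chrom`, `pos`, `delta_snp_index`, `ed4`, `ref`,
#'   `alt`, `category`, `gene_id`, `aa_change`, `description`.
#' @export
build_candidate_table <- function(effects, stats, interval) {
  m <- merge(effects, stats[, c("chrom", "pos", "delta_snp_index", "ed4")],
             by = c("chrom", "pos"))
  keep <- rep(FALSE, nrow(m))
  for (k in seq_len(nrow(interval))) {
    keep <- keep | (m$chrom == interval$chrom[k] &
                      m$pos >= interval$start[k] & m$pos <= interval$end[k])
  }
  m <- m[keep, , drop = FALSE]
  m <- m[order(-abs(m$delta_snp_index), -m$ed4, m$chrom, m$pos), , drop = FALSE]
  rownames(m) <- NULL
  m[, c("chrom", "pos", "delta_snp_index", "ed4", "ref", "alt",
        "category", "gene_id", "aa_change", "description")]
}
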