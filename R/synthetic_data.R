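#' Synthetic genome specification
#'
#' Defaults emulate a compact 12-chromosome plant genome scaled for fast
#' simulation: 5 Mb and 50 cM per chromosome with 40 SNPs/Mb (200 markers
#' per chromosome) segregating between the two inbred parents.
#'
#' @param n_chrom number of chromosomes.
#' @param chrom_length physical length(s) in bp (recycled).
#' @param genetic_length genetic length(s) in cM (recycled).
#' @param snps_per_mb marker density.
#' @return a `genome_spec` list with a `chromosomes` data.frame
#'   (`name`, `length`, `cm`) and `snps_per_mb`.
#' @export
genome_spec <- function(n_chrom = 12, chrom_length = 5e6,
                        genetic_length = 50, snps_per_mb = 40) {
  stopifnot(n_chrom >= 1, all(chrom_length > 0), all(genetic_length > 0),
            snps_per_mb > 0)
  structure(list(
    chromosomes = data.frame(
      name = sprintf("chr%02d", seq_len(n_chrom)),
      length = rep_len(chrom_length, n_chrom),
      cm = rep_len(genetic_length, n_chrom)),
    snps_per_mb = snps_per_mb), class = "genome_spec")
}

#' Causal-locus specification
#'
#' A single incompletely dominant locus: genotype dosage of the
#' purple-parent allele maps 0 to Green, 1 to Purple-green (the intermediate
#' heterozygote) and 2 to Purple, so an F2 segregates 1:2:1 across the three
#' classes.
#'
#' @param chrom chromosome carrying the locus.
#' @param pos position in bp.
#' @param phenotype_map dosage-to-class map (names `"0"`, `"1"`, `"2"`).
#' @param misclassification_rate probability a phenotype is replaced by an
#'   adjacent class; must be in \[0, 0.5).
#' @return a `qtl_spec` list.
#' @export
qtl_spec <- function(chrom = "chr10", pos = 2.5e6,
                     phenotype_map = c("0" = "Green", "1" = "Purple-green",
                                       "2" = "Purple"),
                     misclassification_rate = 0) {
  stopifnot(misclassification_rate >= 0, misclassification_rate < 0.5,
            identical(sort(names(phenotype_map)), c("0", "1", "2")))
  structure(list(chrom = chrom, pos = pos, phenotype_map = phenotype_map,
                 misclassification_rate = misclassification_rate),
            class = "qtl_spec")
}

#' Simulate an F2 population by Haldane meiosis
#'
#' Parents are fixed for alternate alleles at every marker (the purple
#' parent carries the ALT allele genome-wide, the green parent the REF
#' allele). Each F2 gamete is produced by no-interference (Haldane) meiosis:
#' equivalently, along the ordered markers of a chromosome the transmitted
#' parental origin follows a Markov chain whose switch probability between
#' adjacent markers at genetic distance d Morgans is the Haldane
#' recombination fraction c = (1 - exp(-2d)) / 2. Genotype dosage per marker
#' is the number of purple-parent alleles (0, 1 or 2). Marker genetic
#' positions are a linear map of physical position onto the chromosome's
#' genetic length. If a causal locus is given, a marker is placed exactly at
#' its position.
#'
#' @param genome a [genome_spec()].
#' @param n number of F2 individuals.
#' @param qtl optional [qtl_spec()]; must lie inside the genome.
#' @param seed integer seed (RNG state restored on exit).
#' @return an `f2_sim` list: `markers` (data.frame `chrom`, `pos`, `cm`),
#'   `genotypes` (n x markers integer dosage matrix), `qtl`, `seed`.
#' @export
simulate_f2_population <- function(genome, n, qtl = NULL, seed = 1) {
  stopifnot(n >= 1)
  chrs <- genome$chromosomes
  if (!is.null(qtl)) {
    k <- match(qtl$chrom, chrs$name)
    if (is.na(k) || qtl$pos < 1 || qtl$pos > chrs$length[k])
      stop("QTL position outside the genome")
  }
  with_seed(seed, {
    marker_list <- list(); geno_list <- list()
    for (k in seq_len(nrow(chrs))) {
      len <- chrs$length[k]
      m <- max(2L, round(genome$snps_per_mb * len / 1e6))
      pos <- sort(sample.int(len, m))
      if (!is.null(qtl) && qtl$chrom == chrs$name[k] && !(qtl$pos %in% pos))
        pos <- sort(c(pos, qtl$pos))
      cm <- pos / len * chrs$cm[k]
      d_morgan <- diff(cm) / 100
      c_switch <- (1 - exp(-2 * d_morgan)) / 2
      n_gam <- 2L * n
      a <- matrix(0L, n_gam, length(pos))
      a[, 1] <- rbinom(n_gam, 1L, 0.5)
      for (j in seq_along(c_switch)) {
        sw <- rbinom(n_gam, 1L, c_switch[j])
        a[, j + 1L] <- bitwXor(a[, j], sw)
      }
      geno_list[[k]] <- a[seq_len(n), , drop = FALSE] +
        a[n + seq_len(n), , drop = FALSE]
      marker_list[[k]] <- data.frame(chrom = chrs$name[k], pos = pos, cm = cm)
    }
    markers <- do.call(rbind, marker_list)
    rownames(markers) <- NULL
    structure(list(markers = markers,
                   genotypes = do.call(cbind, geno_list),
                   qtl = qtl, seed = seed),
              class = "f2_sim")
  })
}

#' Assign trimodal phenotypes from causal-locus dosages
#'
#' Dosage 2 maps to Purple, 1 to Purple-green, 0 to Green; with probability
#' `misclassification_rate` a class is replaced by an adjacent class
#' (homozygous classes move to the intermediate; the intermediate moves to a
#' random homozygous class).
#'
#' @param dosages integer vector of dosages at the causal locus.
#' @param qtl a [qtl_spec()].
#' @param seed integer seed.
#' @return character vector of classes.
#' @export
assign_phenotypes <- function(dosages, qtl, seed = 1) {
  stopifnot(all(dosages %in% 0:2))
  classes <- unname(qtl$phenotype_map[as.character(dosages)])
  rate <- qtl$misclassification_rate
  if (rate > 0) {
    classes <- with_seed(seed, {
      flip <- runif(length(classes)) < rate
      mid <- qtl$phenotype_map[["1"]]
      homs <- qtl$phenotype_map[c("0", "2")]
      to_mid <- flip & classes != mid
      to_hom <- flip & classes == mid
      classes[to_mid] <- mid
      classes[to_hom] <- sample(homs, sum(to_hom), replace = TRUE)
      classes
    })
  }
  classes
}

#' Select the two extreme-phenotype bulks
#'
#' Uniform random samples without replacement of `bulk_size` individuals
#' from the Purple class and `bulk_size` from the Green class.
#'
#' @param classes phenotype classes (from [assign_phenotypes()]).
#' @param bulk_size individuals per bulk (default 30).
#' @param seed integer seed.
#' @param extremes the two extreme class labels (green then purple).
#' @return list with integer index vectors `bulk_green` and `bulk_purple`.
#' @export
select_bulks <- function(classes, bulk_size = 30, seed = 1,
                         extremes = c("Green", "Purple")) {
  avail <- lapply(extremes, function(cl) which(classes == cl))
  short <- lengths(avail) < bulk_size
  if (any(short))
    stop(sprintf("not enough extreme individuals: %s available (%s needed %d each)",
                 paste(lengths(avail), collapse = "/"),
                 paste(extremes, collapse = "/"), bulk_size))
  with_seed(seed, {
    list(bulk_green = sort(sample(avail[[1]], bulk_size)),
         bulk_purple = sort(sample(avail[[2]], bulk_size)))
  })
}

#' Simulate pooled sequencing reads over the four pools
#'
#' Per bulk and marker the true alternate-allele frequency is the mean
#' genotype dosage over bulk members divided by two; parents are fixed
#' (purple = ALT, green = REF). Site depth per pool is Poisson(`mean_depth`)
#' and alternate read counts are Binomial(depth, f(1-e) + (1-f)e), folding
#' the sequencing error rate e into the allele frequency. Site INFO metrics
#' are emitted at clean pass-filter values (QUAL 1000, MQ 60, QD 25, FS 1,
#' AN 8, SOR 1; DP is the summed pool depth) so the hard filters are
#' exercisable.
#'
#' @param sim an `f2_sim` from [simulate_f2_population()].
#' @param bulks bulk memberships from [select_bulks()].
#' @param mean_depth mean per-pool depth (default 45, matching ~45x pooled
#'   resequencing).
#' @param error_rate per-base error probability (default 0.01).
#' @param seed integer seed.
#' @return list with `variants` (pooled variant data.frame) and `truth`
#'   (data.frame of per-marker true bulk allele frequencies).
#' @export
simulate_pool_reads <- function(sim, bulks, mean_depth = 45,
                                error_rate = 0.01, seed = 1) {
  stopifnot(mean_depth >= 1)
  mk <- sim$markers
  m <- nrow(mk)
  f_true <- list(
    parent_purple = rep(1, m),
    parent_green = rep(0, m),
    bulk_purple = colMeans(sim$genotypes[bulks$bulk_purple, , drop = FALSE]) / 2,
    bulk_green = colMeans(sim$genotypes[bulks$bulk_green, , drop = FALSE]) / 2)
  with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, m, replace = TRUE)
    alt <- vapply(ref, function(b) sample(setdiff(bases, b), 1), "")
    out <- data.frame(chrom = mk$chrom, pos = mk$pos, ref = ref, alt = alt,
                      stringsAsFactors = FALSE)
    total_dp <- 0
    for (role in POOL_ROLES) {
      dp <- rpois(m, mean_depth)
      p <- f_true[[role]] * (1 - error_rate) + (1 - f_true[[role]]) * error_rate
      alt_n <- rbinom(m, dp, p)
      out[[paste0(role, "_ref")]] <- dp - alt_n
      out[[paste0(role, "_alt")]] <- alt_n
      total_dp <- total_dp + dp
    }
    out$dp <- total_dp; out$qual <- 1000; out$mq <- 60; out$qd <- 25
    out$fs <- 1; out$an <- 8; out$sor <- 1
    out <- out[, variant_columns()]
    list(variants = out,
         truth = data.frame(chrom = mk$chrom, pos = mk$pos,
                            f_bulk_green = f_true$bulk_green,
                            f_bulk_purple = f_true$bulk_purple))
  })
}

#' Simulate a complete synthetic BSA-seq experiment
#'
#' End-to-end generator with ground truth: F2 population (default n = 646)
#' under a single incompletely dominant locus, trimodal phenotypes,
#' extreme bulks (default 30 + 30) and pooled reads at ~45x. All randomness
#' derives from one master seed via fixed per-stage offsets (population
#' +101, phenotypes +202, bulks +303, reads +404), so each stage is
#' reproducible in isolation. With `no_qtl = TRUE` phenotypes are drawn
#' 1:2:1 independently of genotype, giving a null experiment.
#'
#' @param genome a [genome_spec()].
#' @param qtl a [qtl_spec()].
#' @param n F2 population size.
#' @param bulk_size individuals per bulk.
#' @param mean_depth mean per-pool sequencing depth.
#' @param error_rate per-base sequencing error rate.
#' @param seed master seed.
#' @param no_qtl simulate the no-QTL null.
#' @return a `bsa_sim` list: `variants` (pooled variant table), `truth`
#'   (causal locus, class counts, bulk memberships, per-marker true bulk
#'   frequencies), `phenotypes`, `sim` (the `f2_sim`), `seed`.
#' @export
simulate_bsa_experiment <- function(genome = genome_spec(),
                                    qtl = qtl_spec(), n = 646,
                                    bulk_size = 30, mean_depth = 45,
                                    error_rate = 0.01, seed = 1,
                                    no_qtl = FALSE) {
  sim <- simulate_f2_population(genome, n, qtl, seed = seed + 101)
  qcol <- which(sim$markers$chrom == qtl$chrom & sim$markers$pos == qtl$pos)
  if (no_qtl) {
    phen <- with_seed(seed + 202, {
      unname(qtl$phenotype_map[as.character(
        sample(0:2, n, replace = TRUE, prob = c(0.25, 0.5, 0.25)))])
    })
  } else {
    phen <- assign_phenotypes(sim$genotypes[, qcol], qtl, seed = seed + 202)
  }
  bulks <- select_bulks(phen, bulk_size, seed = seed + 303,
                        extremes = unname(qtl$phenotype_map[c("0", "2")]))
  reads <- simulate_pool_reads(sim, bulks, mean_depth, error_rate,
                               seed = seed + 404)
  structure(list(
    variants = reads$variants,
    truth = list(qtl_chrom = qtl$chrom, qtl_pos = qtl$pos,
                 class_counts = table(factor(phen, levels = unname(
                   qtl$phenotype_map[c("0", "1", "2")]))),
                 bulks = bulks, frequencies = reads$truth,
                 no_qtl = no_qtl),
    phenotypes = phen, sim = sim, seed = seed), class = "bsa_sim")
}

#' Default VCF sample names for the four simulated pools
#' @return named character vector mapping role to sample name.
#' @export
sim_sample_roles <- function() {
  c(parent_purple = "EP02", parent_green = "EP01",
    bulk_purple = "ZS", bulk_green = "LS")
}

#' Write a pooled variant table as VCF v4.2
#'
#' Minimal plain-text emitter for the simulated four-pool experiment:
#' INFO DP/MQ/QD/FS/AN/SOR, FORMAT AD:DP, samples named as in
#' [sim_sample_roles()]. Round-trips through [read_pooled_vcf()].
#'
#' @param variants pooled variant data.frame.
#' @param path output path (`.vcf`).
#' @param chrom_lengths optional named lengths for `##contig` headers.
#' @export
write_sim_vcf <- function(variants, path, chrom_lengths = NULL) {
  assert_variant_table(variants)
  roles <- sim_sample_roles()
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=bsascan-simulator",
    if (!is.null(chrom_lengths))
      sprintf("##contig=<ID=%s,length=%d>", names(chrom_lengths),
              as.integer(chrom_lengths)),
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Combined depth\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand bias\">",
    "##INFO=<ID=AN,Number=1,Type=Integer,Description=\"Allele number\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", unname(roles)), collapse = "\t"))
  fmt_num <- function(x) ifelse(is.na(x), ".", format(x, trim = TRUE,
                                                      scientific = FALSE))
  info <- sprintf("DP=%s;MQ=%s;QD=%s;FS=%s;AN=%s;SOR=%s",
                  fmt_num(variants$dp), fmt_num(variants$mq),
                  fmt_num(variants$qd), fmt_num(variants$fs),
                  fmt_num(variants$an), fmt_num(variants$sor))
  gt <- sapply(POOL_ROLES, function(role) {
    r <- variants[[paste0(role, "_ref")]]
    a <- variants[[paste0(role, "_alt")]]
    sprintf("%d,%d:%d", as.integer(r), as.integer(a), as.integer(r + a))
  })
  if (nrow(variants) == 1L) gt <- matrix(gt, nrow = 1)
  body <- paste(variants$chrom, as.integer(variants$pos), ".",
                variants$ref, variants$alt, fmt_num(variants$qual),
                "PASS", info, "AD:DP",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Write simulated phenotypes as CSV
#' @param phenotypes character vector of classes.
#' @param path output path.
#' @export
write_phenotypes_csv <- function(phenotypes, path) {
  write.table(data.frame(individual = seq_along(phenotypes),
                         phenotype = phenotypes),
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write simulation ground truth as JSON
#' @param truth the `truth` element of a `bsa_sim`.
#' @param path output path.
#' @export
write_truth_json <- function(truth, path) {
  out <- list(qtl_chrom = truth$qtl_chrom, qtl_pos = truth$qtl_pos,
              class_counts = as.list(truth$class_counts),
              bulk_green = truth$bulks$bulk_green,
              bulk_purple = truth$bulks$bulk_purple,
              no_qtl = truth$no_qtl)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
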