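#' Read a pooled BSA VCF into the variant table
#'
#' Parses a VCF v4.2 (plain or bgzipped) holding the four BSA pools -- two
#' parents and two extreme-phenotype bulks -- into the package's pooled
#' variant data.frame. Only biallelic SNP records are kept; multiallelic and
#' non-SNP records are skipped and counted, as are records lacking a usable
#' per-sample `AD` field.
#'
#' @param path path to the VCF. Per-sample FORMAT must include `AD`
#'   (ref,alt depths); INFO should carry `DP`, `MQ`, `QD`, `FS`, `AN`, `SOR`
#'   for downstream filtering (absent tags become `NA`).
#' @param sample_roles named character vector mapping role to the sample name
#'   in the VCF, e.g. `c(parent_purple = "EP02", parent_green = "EP01",
#'   bulk_purple = "ZS", bulk_green = "LS")`. All four roles are required.
#' @return data.frame with one row per biallelic SNP, sorted by
#'   (chrom, pos): columns `chrom`, `pos`, `ref`, `alt`, the site QC metrics
#'   `dp`, `qual`, `mq`, `qd`, `fs`, `an`, `sor`, and `<role>_ref` /
#'   `<role>_alt` depths for each role. Attribute `skipped` records the
#'   number of records dropped as non-biallelic-SNP or for missing AD.
#' @export
read_pooled_vcf <- function(path, sample_roles) {
  if (!all(POOL_ROLES %in% names(sample_roles)))
    stop("sample_roles must name all four roles: ",
         paste(POOL_ROLES, collapse = ", "))
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- t(fix)   # single-record VCF gives a vector
  fix <- as.data.frame(fix, stringsAsFactors = FALSE)
  if (nrow(fix) == 0L)
    return(empty_variant_table())

  vcf_samples <- colnames(vcf@gt)[-1]
  missing <- setdiff(unname(sample_roles[POOL_ROLES]), vcf_samples)
  if (length(missing))
    stop("samples not present in VCF: ", paste(missing, collapse = ", "))

  pos <- as.numeric(fix$POS)
  # sortedness check on file order, per chromosome
  for (ch in unique(fix$CHROM)) {
    p <- pos[fix$CHROM == ch]
    bad <- which(diff(p) <= 0)
    if (length(bad))
      stop(sprintf("VCF not sorted: %s:%d follows %s:%d",
                   ch, p[bad[1] + 1L], ch, p[bad[1]]))
  }

  is_snp <- !grepl(",", fix$ALT, fixed = TRUE) &
    nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T")
  n_not_snp <- sum(!is_snp)

  ad <- vcfR::extract.gt(vcf, element = "AD")
  if (is.null(dim(ad))) ad <- matrix(ad, nrow = 1, ncol = length(ad),
                                     dimnames = list(NULL, names(ad)))
  parse_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), ",", x), ",", fixed = TRUE)
    r <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
    a <- suppressWarnings(as.numeric(vapply(parts, function(p)
      if (length(p) >= 2L) p[2L] else NA_character_, "")))
    cbind(ref = r, alt = a)
  }
  depth <- lapply(POOL_ROLES, function(role)
    parse_ad(ad[, sample_roles[[role]]]))
  names(depth) <- POOL_ROLES
  ad_ok <- Reduce(`&`, lapply(depth, function(d) complete.cases(d)))
  n_missing_ad <- sum(is_snp & !ad_ok)
  keep <- is_snp & ad_ok

  info_num <- function(tag) {
    suppressWarnings(as.numeric(vcfR::extract.info(vcf, element = tag)))
  }
  out <- data.frame(
    chrom = fix$CHROM, pos = pos, ref = fix$REF, alt = fix$ALT,
    dp = info_num("DP"),
    qual = suppressWarnings(as.numeric(fix$QUAL)),
    mq = info_num("MQ"), qd = info_num("QD"), fs = info_num("FS"),
    an = info_num("AN"), sor = info_num("SOR"),
    stringsAsFactors = FALSE
  )
  for (role in POOL_ROLES) {
    out[[paste0(role, "_ref")]] <- depth[[role]][, "ref"]
    out[[paste0(role, "_alt")]] <- depth[[role]][, "alt"]
  }
  out <- out[keep, , drop = FALSE]
  out <- out[order(out$chrom, out$pos), , drop = FALSE]
  rownames(out) <- NULL
  skipped <- c(non_biallelic_snp = n_not_snp, missing_ad = n_missing_ad)
  if (sum(skipped) > 0)
    message(sprintf("read_pooled_vcf: skipped %d non-biallelic-SNP and %d missing-AD records",
                    skipped[["non_biallelic_snp"]], skipped[["missing_ad"]]))
  attr(out, "skipped") <- skipped
  out
}

empty_variant_table <- function() {
  out <- data.frame(matrix(nrow = 0, ncol = length(variant_columns())))
  names(out) <- variant_columns()
  out$chrom <- character(0); out$ref <- character(0); out$alt <- character(0)
  out
}

#' Hard site-quality filter thresholds
#'
#' Defaults follow the GATK-style hard filters used for "highly reliable"
#' pooled variant calls: total site depth DP in \[60, 1000\], QUAL >= 50,
#' MQ >= 50, QD >= 2, FS <= 40, AN >= 5, SOR <= 5. DP bounds apply to the
#' combined site depth across the four pools (bracketing 4 x ~45x per-pool
#' coverage), not per sample.
#'
#' @param dp_min,dp_max site depth bounds (inclusive).
#' @param qual_min,mq_min,qd_min lower bounds (inclusive).
#' @param fs_max,sor_max upper bounds (inclusive).
#' @param an_min allele-number lower bound (inclusive).
#' @return a `filter_thresholds` list.
#' @export
filter_thresholds <- function(dp_min = 60, dp_max = 1000, qual_min = 50,
                              mq_min = 50, qd_min = 2, fs_max = 40,
                              an_min = 5, sor_max = 5) {
  stopifnot(dp_min < dp_max)
  structure(list(dp_min = dp_min, dp_max = dp_max, qual_min = qual_min,
                 mq_min = mq_min, qd_min = qd_min, fs_max = fs_max,
                 an_min = an_min, sor_max = sor_max),
            class = "filter_thresholds")
}

#' Apply hard site-quality filters
#'
#' A variant is retained iff `dp_min <= DP <= dp_max`, `QUAL >= qual_min`,
#' `MQ >= mq_min`, `QD >= qd_min`, `FS <= fs_max`, `AN >= an_min` and
#' `SOR <= sor_max` (all bounds inclusive). A missing (`NA`) metric fails its
#' rule: a site without evidence of quality is not "highly reliable". Each
#' excluded record is attributed to the first violated rule in the order
#' dp, qual, mq, qd, fs, an, sor.
#'
#' @param variants pooled variant data.frame.
#' @param thresholds a [filter_thresholds()] object.
#' @return list with `retained` (filtered data.frame) and `removed_counts`
#'   (named integer vector of per-rule removals, in rule order).
#' @export
apply_quality_filters <- function(variants, thresholds = filter_thresholds()) {
  assert_variant_table(variants)
  t <- thresholds
  pass_na_false <- function(x) !is.na(x) & x
  rules <- list(
    dp   = pass_na_false(variants$dp >= t$dp_min & variants$dp <= t$dp_max),
    qual = pass_na_false(variants$qual >= t$qual_min),
    mq   = pass_na_false(variants$mq >= t$mq_min),
    qd   = pass_na_false(variants$qd >= t$qd_min),
    fs   = pass_na_false(variants$fs <= t$fs_max),
    an   = pass_na_false(variants$an >= t$an_min),
    sor  = pass_na_false(variants$sor <= t$sor_max)
  )
  pass_all <- Reduce(`&`, rules)
  # first violated rule per excluded record
  first_fail <- rep(NA_integer_, nrow(variants))
  for (i in rev(seq_along(rules))) first_fail[!rules[[i]]] <- i
  removed <- table(factor(first_fail[!pass_all], levels = seq_along(rules),
                          labels = names(rules)))
  retained <- variants[pass_all, , drop = FALSE]
  rownames(retained) <- NULL
  list(retained = retained,
       removed_counts = setNames(as.integer(removed), names(rules)))
}

#' Select parent-informative SNPs
#'
#' Keeps sites where the two parents are each effectively homozygous for
#' opposite alleles: within each parent the minor-allele read fraction is at
#' most `tolerance`, both parents have depth at least `min_parent_depth`, and
#' the parents' major alleles differ.
#'
#' @param variants pooled variant data.frame.
#' @param min_parent_depth minimum parental pool depth (default 10).
#' @param tolerance maximum within-parent minor-allele read fraction
#'   (default 0.05).
#' @return filtered data.frame.
#' @export
select_informative_snps <- function(variants, min_parent_depth = 10,
                                    tolerance = 0.05) {
  assert_variant_table(variants)
  frac_alt <- function(role) {
    tot <- variants[[paste0(role, "_ref")]] + variants[[paste0(role, "_alt")]]
    list(f = variants[[paste0(role, "_alt")]] / tot, tot = tot)
  }
  pp <- frac_alt("parent_purple"); pg <- frac_alt("parent_green")
  homo <- function(f) !is.na(f) & pmin(f, 1 - f) <= tolerance
  keep <- pp$tot >= min_parent_depth & pg$tot >= min_parent_depth &
    homo(pp$f) & homo(pg$f) &
    (round(pp$f) != round(pg$f))   # opposite major alleles
  keep[is.na(keep)] <- FALSE
  out <- variants[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write the pooled variant table as TSV
#' @param variants pooled variant data.frame.
#' @param path output file.
#' @export
write_variants_tsv <- function(variants, path) {
  write.table(variants, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a per-rule filter removal log as TSV
#' @param removed_counts named integer vector from [apply_quality_filters()].
#' @param path output file.
#' @export
write_filter_log <- function(removed_counts, path) {
  write.table(data.frame(rule = names(removed_counts),
                         removed = as.integer(removed_counts)),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
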