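#' SNP-index of a pool
#'
#' Fraction of reads carrying the alternate allele, `alt / (ref + alt)`.
#' Sites with zero depth are undefined and propagate `NA` (never silently 0);
#' such sites are excluded from downstream scans rather than imputed.
#'
#' @param counts a [pool_counts()] object.
#' @return numeric vector in \[0, 1\], `NA` where depth is zero.
#' @examples
#' snp_index(pool_counts(10, 30))  # 0.75
#' @export
snp_index <- function(counts) {
  idx <- counts$alt_depth / counts$total_depth
  idx[counts$total_depth == 0] <- NA_real_
  idx
}

#' Delta-SNP-index between the two bulks
#'
#' Difference of SNP-index values, green (LS) bulk minus purple (ZS) bulk,
#' in that fixed order. The sign therefore depends on which parent carries
#' the ALT allele at a locus; thresholding downstream uses `|delta|` while
#' reports keep the sign. `flip_sign = TRUE` negates the track for plotting.
#'
#' @param green,purple [pool_counts()] for the green and purple bulks.
#' @param flip_sign negate the result (plotting convenience).
#' @return numeric vector in \[-1, 1\], `NA` where either pool has zero depth.
#' @export
delta_snp_index <- function(green, purple, flip_sign = FALSE) {
  d <- snp_index(green) - snp_index(purple)
  if (flip_sign) -d else d
}

#' Euclidean distance between bulk allele-frequency vectors
#'
#' For a biallelic site with alternate-allele frequencies `f_g`, `f_p` in the
#' two bulks, `ED = sqrt((f_g - f_p)^2 + ((1-f_g) - (1-f_p))^2)`, i.e.
#' `sqrt(2) * |f_g - f_p|`. Maximum `sqrt(2)` at opposite fixation.
#'
#' @inheritParams delta_snp_index
#' @return numeric vector in \[0, sqrt(2)\].
#' @export
ed <- function(green, purple) {
  dalt <- snp_index(green) - snp_index(purple)
  sqrt(2 * dalt^2)
}

#' Fourth power of the Euclidean distance (ED^4)
#'
#' `ed(...)^4`; for biallelic sites identically `4 * (delta f_alt)^4`, so the
#' maximum is 4 at opposite fixation. Raising to the fourth power suppresses
#' background noise relative to linked signal.
#'
#' @inheritParams delta_snp_index
#' @return numeric vector in \[0, 4\].
#' @examples
#' # frequencies 0.99 vs 0.01: delta f = 0.98, ED^4 = 4 * 0.98^4 = 3.69
#' ed4(pool_counts(1, 99), pool_counts(99, 1))
#' @export
ed4 <- function(green, purple) {
  ed(green, purple)^4
}

#' Per-site BSA statistics track
#'
#' Appends SNP-index for each bulk, delta-SNP-index (green minus purple),
#' ED and ED^4 to a pooled variant table, plus the mean per-bulk depth used
#' for matching the simulated null.
#'
#' @param variants pooled variant data.frame.
#' @return the input with columns `snp_index_green`, `snp_index_purple`,
#'   `delta_snp_index`, `ed`, `ed4`, `bulk_depth` appended.
#' @export
site_stats <- function(variants) {
  assert_variant_table(variants)
  g <- variant_counts(variants, "bulk_green")
  p <- variant_counts(variants, "bulk_purple")
  variants$snp_index_green <- snp_index(g)
  variants$snp_index_purple <- snp_index(p)
  variants$delta_snp_index <- delta_snp_index(g, p)
  variants$ed <- ed(g, p)
  variants$ed4 <- ed4(g, p)
  variants$bulk_depth <- (g$total_depth + p$total_depth) / 2
  variants
}

#' Mendelian segregation chi-square test
#'
#' Pearson goodness-of-fit test of three phenotype class counts against an
#' expected ratio (1:2:1 for an incompletely dominant single locus in an F2).
#' Expected counts are `total * weight / sum(weights)`; df = classes - 1; the
#' p-value is the upper tail of the chi-square distribution, with no
#' continuity correction.
#'
#' @param observed integer vector of three class counts
#'   (green, intermediate, purple).
#' @param ratio positive expected weights, default `c(1, 2, 1)`.
#' @return a `segregation_result` list: `observed`, `expected_ratio`,
#'   `expected`, `chi2`, `df`, `p_value`.
#' @examples
#' segregation_chi_square(c(177, 325, 144))  # chi2 = 3.40, p = 0.18
#' @export
segregation_chi_square <- function(observed, ratio = c(1, 2, 1)) {
  stopifnot(length(observed) == length(ratio), all(observed >= 0),
            all(ratio > 0))
  if (sum(observed) == 0) stop("total observed count is zero")
  expected <- sum(observed) * ratio / sum(ratio)
  chi2 <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  structure(list(observed = observed, expected_ratio = ratio,
                 expected = expected, chi2 = chi2, df = df,
                 p_value = pchisq(chi2, df, lower.tail = FALSE)),
            class = "segregation_result")
}

#' @export
print.segregation_result <- function(x, ...) {
  cat(sprintf("Segregation test: observed (%s) vs ratio %s\n",
              paste(x$observed, collapse = ", "),
              paste(x$expected_ratio, collapse = ":")))
  cat(sprintf("  chi2 = %.2f, df = %d, p = %.2f\n", x$chi2, x$df, x$p_value))
  invisible(x)
}

#' Write the per-site statistics track as TSV
#' @param stats output of [site_stats()].
#' @param path output file.
#' @export
write_site_stats_tsv <- function(stats, path) {
  cols <- c("chrom", "pos", "ref", "alt",
            "bulk_green_ref", "bulk_green_alt",
            "bulk_purple_ref", "bulk_purple_alt",
            "snp_index_green", "snp_index_purple",
            "delta_snp_index", "ed", "ed4")
  write.table(stats[, cols], path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
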