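#' Pipeline run configuration
#'
#' Exactly one input source must be active: either the paths of a real
#' experiment (`vcf`, plus optional `gff3`/`fasta` for annotation) or a
#' simulation request (`simulate = TRUE`). The configuration is serialized
#' verbatim into the run log.
#'
#' @param vcf,gff3,fasta input paths (real-data mode). `gff3`/`fasta` are
#'   optional; without them annotation is skipped.
#' @param sample_roles role-to-sample-name map for the VCF (defaults to the
#'   simulator's names).
#' @param phenotype_csv optional CSV of individual phenotypes; when given,
#'   the 1:2:1 segregation test is included in the summary.
#' @param simulate run on a fresh synthetic experiment instead of files.
#' @param sim_args list of arguments passed to [simulate_bsa_experiment()].
#' @param thresholds a [filter_thresholds()].
#' @param params a [scan_params()].
#' @param min_parent_depth,parent_tolerance parent-informativeness settings.
#' @param bulk_size individuals per bulk (null-CI matching).
#' @param flank annotation flank in bp.
#' @param max_gap interval-merge gap in bp.
#' @param top_n maximum candidate-table rows in the summary.
#' @param out_dir output directory.
#' @param seed master seed.
#' @return a `run_config` list.
#' @export
run_config <- function(vcf = NULL, gff3 = NULL, fasta = NULL,
                       sample_roles = sim_sample_roles(),
                       phenotype_csv = NULL,
                       simulate = FALSE, sim_args = list(),
                       thresholds = filter_thresholds(),
                       params = scan_params(),
                       min_parent_depth = 10, parent_tolerance = 0.05,
                       bulk_size = 30, flank = 5000, max_gap = 5e5,
                       top_n = 20, out_dir = tempfile("bsascan_run_"),
                       seed = 1) {
  if (simulate == !is.null(vcf))
    stop("exactly one of a VCF path or simulate = TRUE must be given")
  structure(list(vcf = vcf, gff3 = gff3, fasta = fasta,
                 sample_roles = sample_roles, phenotype_csv = phenotype_csv,
                 simulate = simulate, sim_args = sim_args,
                 thresholds = thresholds, params = params,
                 min_parent_depth = min_parent_depth,
                 parent_tolerance = parent_tolerance,
                 bulk_size = bulk_size, flank = flank, max_gap = max_gap,
                 top_n = top_n, out_dir = out_dir, seed = seed),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Scalar keys mirror the [run_config()] arguments; `thresholds` and
#' `params` may be given as nested maps of the corresponding constructor
#' arguments.
#'
#' @param path YAML file.
#' @param ... overrides applied after the file is read (CLI flags).
#' @return a `run_config`.
#' @export
read_run_config <- function(path, ...) {
  # YAML 1.1 resolves bare n/y as booleans; keep them literal so keys like
  # the population size `n` survive
  handlers <- list(
    "bool#yes" = function(x) if (tolower(x) == "y") x else TRUE,
    "bool#no" = function(x) if (tolower(x) == "n") x else FALSE)
  y <- yaml::read_yaml(path, handlers = handlers)
  if (!is.null(y$thresholds)) y$thresholds <- do.call(filter_thresholds, y$thresholds)
  if (!is.null(y$params)) y$params <- do.call(scan_params, y$params)
  if (!is.null(y$sample_roles)) y$sample_roles <- unlist(y$sample_roles)
  over <- list(...)
  y[names(over)] <- over
  do.call(run_config, y)
}

#' Run the full BSA pipeline
#'
#' Executes variant import (or simulation), quality filtering,
#' parent-informative SNP selection, per-site statistics, the genome scan,
#' interval calling per method, consensus intersection, and (when gene
#' models are supplied or simulated annotation is skipped) the candidate
#' table. All tabular outputs, the filter ledger, scan figures and a
#' markdown summary are written under `config$out_dir`; outputs are
#' reproducible byte-for-byte from the configuration and seed.
#'
#' @param config a [run_config()].
#' @param write_plots write per-chromosome scan figures (default TRUE; PDF).
#' @return a `bsa_run` list: `config`, `variants`, `filter_log`, `sites`,
#'   `scan`, `intervals` (per-method), `consensus`, `candidates` (or NULL),
#'   `segregation` (or NULL), `truth` (simulation only), `summary_path`.
#' @export
run_pipeline <- function(config, write_plots = TRUE) {
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  truth <- NULL
  phenotypes <- NULL
  if (config$simulate) {
    sim <- do.call(simulate_bsa_experiment,
                   c(config$sim_args, list(seed = config$seed)))
    raw <- sim$variants
    truth <- sim$truth
    phenotypes <- sim$phenotypes
    write_sim_vcf(raw, file.path(config$out_dir, "simulated.vcf"))
    write_phenotypes_csv(phenotypes,
                         file.path(config$out_dir, "phenotypes.csv"))
    write_truth_json(truth, file.path(config$out_dir, "truth.json"))
  } else {
    raw <- read_pooled_vcf(config$vcf, config$sample_roles)
    if (!is.null(config$phenotype_csv))
      phenotypes <- read.table(config$phenotype_csv, sep = ",",
                               header = TRUE)$phenotype
  }

  filt <- apply_quality_filters(raw, config$thresholds)
  informative <- select_informative_snps(filt$retained,
                                         config$min_parent_depth,
                                         config$parent_tolerance)
  write_filter_log(filt$removed_counts,
                   file.path(config$out_dir, "filter_log.tsv"))
  write_variants_tsv(informative,
                     file.path(config$out_dir, "filtered_variants.tsv"))

  sites <- site_stats(informative)
  write_site_stats_tsv(sites, file.path(config$out_dir, "site_stats.tsv"))

  scan <- genome_scan(sites, config$params, bulk_size = config$bulk_size,
                      seed = config$seed)
  write_windows_tsv(scan, file.path(config$out_dir, "windows.tsv"))

  iv_delta <- call_intervals(scan$windows, "delta_sig", config$max_gap,
                             sites = scan$sites,
                             site_stat = "delta_snp_index",
                             site_threshold = scan$delta_site_threshold,
                             method = "delta")
  iv_ed4 <- call_intervals(scan$windows, "ed4_sig", config$max_gap,
                           sites = scan$sites, site_stat = "ed4",
                           site_threshold = scan$ed4_threshold,
                           method = "ed4")
  consensus <- intersect_interval_sets(iv_delta, iv_ed4)
  intervals <- rbind(iv_delta, iv_ed4, consensus)
  write_intervals(intervals,
                  bed_path = file.path(config$out_dir, "intervals.bed"),
                  tsv_path = file.path(config$out_dir, "intervals.tsv"))

  candidates <- NULL
  if (!is.null(config$gff3) && !is.null(config$fasta) && nrow(consensus)) {
    models <- load_gene_models(config$gff3, config$fasta)
    in_iv <- rep(FALSE, nrow(sites))
    for (k in seq_len(nrow(consensus)))
      in_iv <- in_iv | (sites$chrom == consensus$chrom[k] &
                          sites$pos >= consensus$start[k] &
                          sites$pos <= consensus$end[k])
    effects <- classify_variant_location(sites[in_iv, , drop = FALSE],
                                         models, config$flank)
    candidates <- build_candidate_table(effects, sites, consensus)
    write.table(candidates, file.path(config$out_dir, "candidates.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }

  segregation <- NULL
  if (!is.null(phenotypes)) {
    lev <- c("Green", "Purple-green", "Purple")
    if (all(phenotypes %in% lev))
      segregation <- segregation_chi_square(
        as.integer(table(factor(phenotypes, levels = lev))))
  }

  if (write_plots) {
    try(plot_scan(scan, file.path(config$out_dir, "scan.pdf")), silent = TRUE)
  }

  run <- structure(list(config = config, variants = raw,
                        filter_log = filt$removed_counts, sites = sites,
                        scan = scan, intervals = intervals,
                        consensus = consensus, candidates = candidates,
                        segregation = segregation, truth = truth),
                   class = "bsa_run")
  run$summary_path <- summarize_run(run,
                                    file.path(config$out_dir, "summary.md"))
  run
}

#' Write a human-readable run summary
#'
#' One markdown document per run: the filter ledger, SNP counts surviving
#' each stage, per-method and consensus intervals with widths in Mb, the top
#' candidate SNPs and, when phenotypes were supplied, the 1:2:1 segregation
#' test.
#'
#' @param run a `bsa_run` from [run_pipeline()].
#' @param path output file.
#' @return the path, invisibly.
#' @export
summarize_run <- function(run, path) {
  fmt_iv <- function(iv) {
    if (!nrow(iv)) return("- none")
    sprintf("- %s:%s-%s (%.2f Mb, method %s, %s supporting SNPs)",
            iv$chrom, format(iv$start, big.mark = ",", trim = TRUE),
            format(iv$end, big.mark = ",", trim = TRUE),
            interval_width_mb(iv), iv$method, iv$n_supporting_snps)
  }
  lines <- c(
    "# BSA scan summary", "",
    sprintf("Input SNPs: %d; after quality filters: %d; parent-informative: %d",
            nrow(run$variants),
            nrow(run$variants) - sum(run$filter_log), nrow(run$sites)),
    "", "## Filter ledger",
    sprintf("- %s: %d removed", names(run$filter_log), run$filter_log),
    "", "## Thresholds",
    sprintf("- ED^4 top-%g%% threshold: %.4f",
            run$scan$params$top_fraction * 100, run$scan$ed4_threshold),
    sprintf("- |delta-SNP-index| null %g%% bound (mean depth): %.4f",
            min(run$scan$params$ci_levels) * 100,
            run$scan$delta_site_threshold),
    "", "## Candidate intervals",
    fmt_iv(run$intervals[run$intervals$method != "consensus", , drop = FALSE]),
    "", "## Consensus QTL",
    if (nrow(run$consensus)) fmt_iv(run$consensus) else "- no QTL found")
  if (!is.null(run$segregation)) {
    s <- run$segregation
    lines <- c(lines, "", "## Segregation test",
               sprintf("- observed %s vs %s: chi2 = %.2f, df = %d, p = %.2f",
                       paste(s$observed, collapse = "/"),
                       paste(s$expected_ratio, collapse = ":"),
                       s$chi2, s$df, s$p_value))
  }
  if (!is.null(run$candidates) && nrow(run$candidates)) {
    top <- head(run$candidates, run$config$top_n)
    lines <- c(lines, "", "## Top candidate SNPs",
               "| pos | delta | ED^4 | REF | ALT | type | gene |",
               "|---|---|---|---|---|---|---|",
               sprintf("| %s:%d | %.3f | %.3f | %s | %s | %s | %s |",
                       top$chrom, top$pos, top$delta_snp_index, top$ed4,
                       top$ref, top$alt, top$category, top$gene_id))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Per-chromosome scan figures
#'
#' Draws the delta-SNP-index and ED^4 tracks: raw per-SNP points, the LOESS
#' fitted line, and the significance thresholds (simulated null bound for
#' delta; top-percentile line for ED^4).
#'
#' @param scan a `bsa_scan` object.
#' @param path output PDF path (`NULL` returns the plot object only).
#' @return the ggplot object, invisibly.
#' @export
plot_scan <- function(scan, path = NULL) {
  s <- scan$sites
  long <- rbind(
    data.frame(chrom = s$chrom, pos = s$pos, value = s$delta_snp_index,
               fitted = s$fitted_delta, stat = "delta-SNP-index",
               threshold = scan$delta_site_threshold),
    data.frame(chrom = s$chrom, pos = s$pos, value = s$ed4,
               fitted = s$fitted_ed4, stat = "ED^4",
               threshold = scan$ed4_threshold))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = pos / 1e6)) +
    ggplot2::geom_point(ggplot2::aes(y = value), size = 0.3,
                        alpha = 0.4, colour = "grey40") +
    ggplot2::geom_line(ggplot2::aes(y = fitted), colour = "red",
                       na.rm = TRUE) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = threshold),
                        linetype = "dashed", colour = "blue") +
    ggplot2::facet_grid(stat ~ chrom, scales = "free", space = "free_x") +
    ggplot2::labs(x = "position (Mb)", y = NULL) +
    ggplot2::theme_bw(base_size = 8)
  if (!is.null(path)) {
    grDevices::pdf(path, width = 12, height = 5)
    print(p)
    grDevices::dev.off()
  }
  invisible(p)
}
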