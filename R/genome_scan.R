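#' Genome-scan parameters
#'
#' @param window_size sliding-window size in bp (default 1 Mb).
#' @param step_size window step in bp (default 500 kb); must not exceed
#'   `window_size`.
#' @param min_snps_per_window windows with fewer defined SNPs carry undefined
#'   means and never contribute to thresholds or intervals (default 10).
#' @param loess_span LOESS span as a fraction of a chromosome's points
#'   (default 0.1); each local fit is floored at 10 points.
#' @param top_fraction fraction of ED^4 values defining the genome-wide
#'   significance threshold (default 0.01, i.e. the top 1%).
#' @param ci_levels confidence levels for the simulated delta-SNP-index null
#'   (default 0.95 and 0.99).
#' @return a `scan_params` list.
#' @export
scan_params <- function(window_size = 1e6, step_size = 5e5,
                        min_snps_per_window = 10, loess_span = 0.1,
                        top_fraction = 0.01, ci_levels = c(0.95, 0.99)) {
  stopifnot(step_size <= window_size, step_size >= 1,
            top_fraction > 0, top_fraction < 1)
  structure(list(window_size = window_size, step_size = step_size,
                 min_snps_per_window = min_snps_per_window,
                 loess_span = loess_span, top_fraction = top_fraction,
                 ci_levels = sort(ci_levels)),
            class = "scan_params")
}

#' Enumerate sliding windows along a chromosome
#'
#' Windows are anchored at position 1 and advance by `step_size`; a window is
#' emitted iff its start lies on the chromosome, and the final window is
#' truncated at `chrom_length`.
#'
#' @param chrom_length chromosome length in bp.
#' @param params a [scan_params()] object.
#' @return data.frame with `start`, `end` (1-based inclusive).
#' @export
make_windows <- function(chrom_length, params = scan_params()) {
  stopifnot(chrom_length >= 1)
  starts <- seq(1, chrom_length, by = params$step_size)
  data.frame(start = starts,
             end = pmin(starts + params$window_size - 1, chrom_length))
}

#' Sliding-window means of per-site statistics
#'
#' Per window, the arithmetic mean of delta-SNP-index and ED^4 over contained
#' SNPs with defined statistics. Windows holding fewer than
#' `min_snps_per_window` defined SNPs carry `NA` means and are excluded from
#' thresholding and interval calling.
#'
#' @param sites output of [site_stats()], sorted by (chrom, pos).
#' @param params a [scan_params()] object.
#' @param chrom_lengths optional named vector of chromosome lengths; defaults
#'   to the maximum SNP position per chromosome.
#' @return data.frame with `chrom`, `start`, `end`, `n_snps`, `mean_delta`,
#'   `mean_ed4`, `mean_depth`.
#' @export
window_scan <- function(sites, params = scan_params(), chrom_lengths = NULL) {
  chroms <- unique(sites$chrom)
  if (is.null(chrom_lengths)) {
    chrom_lengths <- vapply(chroms, function(ch)
      max(sites$pos[sites$chrom == ch]), numeric(1))
  }
  res <- lapply(chroms, function(ch) {
    s <- sites[sites$chrom == ch, , drop = FALSE]
    w <- make_windows(chrom_lengths[[ch]], params)
    hits <- IRanges::findOverlaps(
      IRanges::IRanges(s$pos, s$pos), IRanges::IRanges(w$start, w$end))
    site_i <- S4Vectors::queryHits(hits)
    win_i <- S4Vectors::subjectHits(hits)
    defined <- !is.na(s$delta_snp_index[site_i])
    site_i <- site_i[defined]; win_i <- win_i[defined]
    agg <- function(v) {
      out <- rep(NA_real_, nrow(w))
      if (length(win_i)) {
        m <- tapply(v[site_i], win_i, mean)
        out[as.integer(names(m))] <- as.numeric(m)
      }
      out
    }
    n <- integer(nrow(w))
    if (length(win_i)) {
      tab <- table(win_i)
      n[as.integer(names(tab))] <- as.integer(tab)
    }
    w$chrom <- ch
    w$n_snps <- n
    w$mean_delta <- agg(s$delta_snp_index)
    w$mean_ed4 <- agg(s$ed4)
    w$mean_depth <- agg(s$bulk_depth)
    low <- n < params$min_snps_per_window
    w$mean_delta[low] <- NA_real_
    w$mean_ed4[low] <- NA_real_
    w[, c("chrom", "start", "end", "n_snps", "mean_delta", "mean_ed4",
          "mean_depth")]
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' LOESS smoothing of a statistic along one chromosome
#'
#' Degree-1 locally weighted regression (tricube weights) fitted to the
#' defined points and evaluated at every input position. The span is floored
#' so each local fit sees at least 10 points. Deterministic for fixed input.
#'
#' @param positions bp positions (one chromosome).
#' @param values statistic values (`NA` allowed).
#' @param span fraction of points per local fit (default 0.1).
#' @return fitted values at `positions`; all-`NA` with a warning when fewer
#'   than 10 defined points are available.
#' @export
loess_smooth <- function(positions, values, span = 0.1) {
  ok <- !is.na(values) & !is.na(positions)
  if (sum(ok) < 10) {
    warning("fewer than 10 defined points; chromosome skipped")
    return(rep(NA_real_, length(positions)))
  }
  fit <- chrom_loess(positions[ok], values[ok], span)
  as.numeric(predict(fit, data.frame(x = positions)))
}

# internal: loess fit with span floored at 10 local points
chrom_loess <- function(x, y, span) {
  span_used <- max(span, min(1, 10 / length(x)))
  loess(y ~ x, data = data.frame(x = x, y = y), span = span_used,
        degree = 1, family = "gaussian", surface = "direct")
}

#' Top-fraction empirical significance threshold
#'
#' The empirical quantile at probability `1 - fraction` with linear
#' interpolation between order statistics, so the top `fraction` of values
#' across the genome lies above it.
#'
#' @param values statistic values (`NA` dropped).
#' @param fraction tail fraction (default 0.01).
#' @return the threshold (scalar).
#' @examples
#' top_fraction_threshold(1:100, 0.01)  # 99.01
#' @export
top_fraction_threshold <- function(values, fraction = 0.01) {
  values <- values[!is.na(values)]
  if (!length(values)) stop("no defined values for thresholding")
  if (length(values) < 1 / fraction)
    warning(sprintf("only %d defined values for a top-%g threshold",
                    length(values), fraction))
  quantile(values, probs = 1 - fraction, names = FALSE, type = 7)
}

#' Simulated null distribution of |delta-SNP-index|
#'
#' Monte-Carlo null for an F2 design: each bulk's true alternate-allele
#' frequency is the mean genotype dosage of `bulk_size` individuals drawn
#' under the null (dosages 0, 1/2, 1 with probability 1/4, 1/2, 1/4 --
#' equivalently 2*`bulk_size` independent Bernoulli(1/2) alleles), then read
#' counts are drawn binomially at the given depth and |delta| computed
#' between the two bulks. Upper quantiles of |delta| give the confidence
#' bounds used to flag windows.
#'
#' @param bulk_size individuals per bulk.
#' @param depth reads per site per bulk.
#' @param population_type cross design; only `"F2"` is implemented.
#' @param n_reps Monte-Carlo replicates (default 10000).
#' @param ci_levels quantile levels (default 0.95, 0.99).
#' @param seed integer seed; the RNG state is restored on exit.
#' @return a `null_ci` list: `bulk_size`, `population_type`, `depth`,
#'   `quantiles` (named by level), `n_reps`, `seed`.
#' @export
simulate_delta_null <- function(bulk_size, depth, population_type = "F2",
                                n_reps = 10000, ci_levels = c(0.95, 0.99),
                                seed = 1) {
  if (!identical(population_type, "F2"))
    stop("unknown population_type: ", population_type)
  stopifnot(bulk_size >= 1, depth >= 1, n_reps >= 1)
  dabs <- with_seed(seed, {
    f1 <- rbinom(n_reps, 2 * bulk_size, 0.5) / (2 * bulk_size)
    f2 <- rbinom(n_reps, 2 * bulk_size, 0.5) / (2 * bulk_size)
    abs(rbinom(n_reps, depth, f1) / depth - rbinom(n_reps, depth, f2) / depth)
  })
  q <- quantile(dabs, probs = ci_levels, names = FALSE, type = 7)
  structure(list(bulk_size = bulk_size, population_type = population_type,
                 depth = depth,
                 quantiles = setNames(q, as.character(ci_levels)),
                 n_reps = n_reps, seed = seed),
            class = "null_ci")
}

# internal: evaluate code under a temporary seed, restoring RNG state
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# internal: tabulate null quantiles over a grid of depths
delta_null_grid <- function(bulk_size, depths, n_reps, ci_levels, seed) {
  depths <- sort(unique(depths))
  rows <- lapply(seq_along(depths), function(i) {
    ci <- simulate_delta_null(bulk_size, depths[i], n_reps = n_reps,
                              ci_levels = ci_levels, seed = seed + i)
    c(depth = depths[i], ci$quantiles)
  })
  as.data.frame(do.call(rbind, rows))
}

#' Full genome scan with smoothing, thresholds and significance flags
#'
#' Runs the complete scan over a per-site statistics track: per-chromosome
#' LOESS smoothing of delta-SNP-index and ED^4, sliding-window means, the
#' genome-wide top-fraction ED^4 threshold on raw per-SNP values, and a
#' simulated |delta| null confidence interval matched to each window's mean
#' bulk depth. Windows are flagged significant per method when the fitted
#' value at the window midpoint exceeds the method's threshold.
#'
#' @param sites output of [site_stats()] (typically after
#'   [apply_quality_filters()] and [select_informative_snps()]).
#' @param params a [scan_params()] object.
#' @param bulk_size individuals per bulk, for the simulated null (default 30).
#' @param chrom_lengths optional named chromosome lengths.
#' @param n_reps Monte-Carlo replicates per null grid depth (default 2000).
#' @param seed seed for the null simulation.
#' @return a `bsa_scan` list: `sites` (with `fitted_delta`, `fitted_ed4`),
#'   `windows` (with fitted midpoint values, `ci95`/`ci99` where requested,
#'   and `delta_sig` / `ed4_sig` flags), `ed4_threshold`,
#'   `delta_site_threshold` (null quantile at the genome-wide mean bulk
#'   depth, used for boundary snapping), `null_grid`, `params`, `seed`.
#' @export
genome_scan <- function(sites, params = scan_params(), bulk_size = 30,
                        chrom_lengths = NULL, n_reps = 2000, seed = 1) {
  if (!"delta_snp_index" %in% names(sites))
    stop("sites must come from site_stats()")
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  windows <- window_scan(sites, params, chrom_lengths)

  # per-chromosome LOESS, evaluated at SNPs and at window midpoints
  sites$fitted_delta <- NA_real_
  sites$fitted_ed4 <- NA_real_
  mid <- floor((windows$start + windows$end) / 2)
  windows$fitted_delta <- NA_real_
  windows$fitted_ed4 <- NA_real_
  for (ch in unique(sites$chrom)) {
    si <- which(sites$chrom == ch)
    wi <- which(windows$chrom == ch)
    ok <- si[!is.na(sites$delta_snp_index[si])]
    if (length(ok) < 10) {
      warning(sprintf("chromosome %s has fewer than 10 defined SNPs; not smoothed", ch))
      next
    }
    for (stat in c("delta_snp_index", "ed4")) {
      fit <- chrom_loess(sites$pos[ok], sites[[stat]][ok], params$loess_span)
      col <- if (stat == "ed4") "fitted_ed4" else "fitted_delta"
      sites[[col]][si] <- as.numeric(predict(fit, data.frame(x = sites$pos[si])))
      windows[[col]][wi] <- as.numeric(predict(fit, data.frame(x = mid[wi])))
    }
  }

  ed4_threshold <- top_fraction_threshold(sites$ed4, params$top_fraction)

  # null CI per window, matched to mean bulk depth (grid at 5x resolution)
  depth_bin <- pmax(5, round(windows$mean_depth / 5) * 5)
  grid <- delta_null_grid(bulk_size, depth_bin[!is.na(depth_bin)],
                          n_reps = n_reps, ci_levels = params$ci_levels,
                          seed = seed)
  for (lev in params$ci_levels) {
    col <- paste0("ci", sub("^0\\.", "", as.character(lev)))
    windows[[col]] <- grid[[as.character(lev)]][match(depth_bin, grid$depth)]
  }
  ci_main <- paste0("ci",
                    sub("^0\\.", "", as.character(min(params$ci_levels))))

  defined <- windows$n_snps >= params$min_snps_per_window
  windows$delta_sig <- defined & !is.na(windows$fitted_delta) &
    abs(windows$fitted_delta) > windows[[ci_main]]
  windows$ed4_sig <- defined & !is.na(windows$fitted_ed4) &
    windows$fitted_ed4 > ed4_threshold
  windows$delta_sig[is.na(windows$delta_sig)] <- FALSE
  windows$ed4_sig[is.na(windows$ed4_sig)] <- FALSE

  mean_depth <- mean(sites$bulk_depth, na.rm = TRUE)
  delta_site_threshold <- simulate_delta_null(
    bulk_size, max(5, round(mean_depth)), n_reps = max(n_reps, 2000),
    ci_levels = min(params$ci_levels), seed = seed)$quantiles[[1]]

  structure(list(sites = sites, windows = windows,
                 ed4_threshold = ed4_threshold,
                 delta_site_threshold = delta_site_threshold,
                 null_grid = grid, bulk_size = bulk_size,
                 params = params, seed = seed),
            class = "bsa_scan")
}

#' Write the window track as TSV
#' @param scan a `bsa_scan` object from [genome_scan()].
#' @param path output file.
#' @export
write_windows_tsv <- function(scan, path) {
  write.table(scan$windows, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
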