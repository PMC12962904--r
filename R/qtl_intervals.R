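#' Call candidate intervals from flagged scan windows
#'
#' Maximal runs of significant windows (per method) are merged, allowing
#' non-significant gaps of at most `max_gap` bp so that a single undefined
#' window does not split a QTL. Interval boundaries are then snapped to the
#' first and last above-threshold raw SNP inside each merged run, which is
#' how SNP-coordinate QTL boundaries arise; the window-edge bounds are kept
#' alongside.
#'
#' @param windows window table with a logical flag column (from
#'   [genome_scan()]).
#' @param flag_col name of the flag column (`"delta_sig"` or `"ed4_sig"`).
#' @param max_gap maximum unflagged gap bridged, in bp (default 500 kb, one
#'   step).
#' @param sites optional per-site statistics for boundary snapping.
#' @param site_stat per-site statistic column used for snapping
#'   (`"delta_snp_index"` uses `|value|`; `"ed4"` the raw value).
#' @param site_threshold threshold a raw SNP must exceed to anchor a
#'   boundary.
#' @param method label stored on the output (`"delta"`, `"ed4"`).
#' @return data.frame of intervals: `chrom`, `start`, `end` (1-based
#'   inclusive, SNP-snapped when sites are given), `window_start`,
#'   `window_end` (merged window-edge bounds), `method`,
#'   `n_supporting_snps`. Zero rows when nothing is flagged.
#' @export
call_intervals <- function(windows, flag_col, max_gap = 5e5,
                           sites = NULL, site_stat = NULL,
                           site_threshold = NULL, method = flag_col) {
  stopifnot(flag_col %in% names(windows))
  out <- list()
  for (ch in unique(windows$chrom)) {
    w <- windows[windows$chrom == ch, , drop = FALSE]
    w <- w[order(w$start), , drop = FALSE]
    flagged <- w[which(w[[flag_col]]), , drop = FALSE]
    if (!nrow(flagged)) next
    # merge flagged windows whose spans are within max_gap of each other
    run_start <- flagged$start[1]; run_end <- flagged$end[1]
    runs <- list()
    if (nrow(flagged) > 1) {
      for (i in 2:nrow(flagged)) {
        if (flagged$start[i] - run_end - 1 <= max_gap) {
          run_end <- max(run_end, flagged$end[i])
        } else {
          runs[[length(runs) + 1]] <- c(run_start, run_end)
          run_start <- flagged$start[i]; run_end <- flagged$end[i]
        }
      }
    }
    runs[[length(runs) + 1]] <- c(run_start, run_end)
    for (r in runs) {
      start <- r[1]; end <- r[2]
      snap_start <- start; snap_end <- end; n_supp <- NA_integer_
      if (!is.null(sites) && !is.null(site_stat)) {
        s <- sites[sites$chrom == ch & sites$pos >= start &
                     sites$pos <= end, , drop = FALSE]
        v <- s[[site_stat]]
        if (site_stat == "delta_snp_index") v <- abs(v)
        hot <- !is.na(v) & v > site_threshold
        n_supp <- sum(hot)
        if (any(hot)) {
          snap_start <- min(s$pos[hot])
          snap_end <- max(s$pos[hot])
        }
      }
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = snap_start, end = snap_end,
        window_start = start, window_end = end,
        method = method, n_supporting_snps = n_supp)
    }
  }
  if (!length(out)) return(empty_intervals())
  res <- do.call(rbind, out)
  res[order(res$chrom, res$start), , drop = FALSE]
}

empty_intervals <- function() {
  data.frame(chrom = character(0), start = numeric(0), end = numeric(0),
             window_start = numeric(0), window_end = numeric(0),
             method = character(0), n_supporting_snps = integer(0))
}

#' Intersect two interval sets into a consensus
#'
#' Pairwise per-chromosome overlaps (max of starts, min of ends) where
#' positive; this is the consensus of the delta-SNP-index and ED^4 candidate
#' intervals. Overlap arithmetic is delegated to IRanges.
#'
#' @param a,b interval data.frames (as from [call_intervals()]).
#' @return consensus intervals with `method = "consensus"`;
#'   `n_supporting_snps` is the minimum of the overlapping pair's counts.
#' @export
intersect_interval_sets <- function(a, b) {
  if (!nrow(a) || !nrow(b)) return(empty_intervals())
  out <- list()
  for (ch in intersect(unique(a$chrom), unique(b$chrom))) {
    ra <- a[a$chrom == ch, , drop = FALSE]
    rb <- b[b$chrom == ch, , drop = FALSE]
    ia <- IRanges::IRanges(ra$start, ra$end)
    ib <- IRanges::IRanges(rb$start, rb$end)
    hits <- IRanges::findOverlaps(ia, ib)
    if (!length(hits)) next
    qi <- S4Vectors::queryHits(hits); si <- S4Vectors::subjectHits(hits)
    ov <- IRanges::pintersect(ia[qi], ib[si])
    out[[length(out) + 1]] <- data.frame(
      chrom = ch,
      start = IRanges::start(ov), end = IRanges::end(ov),
      window_start = pmax(ra$window_start[qi], rb$window_start[si]),
      window_end = pmin(ra$window_end[qi], rb$window_end[si]),
      method = "consensus",
      n_supporting_snps = pmin(ra$n_supporting_snps[qi],
                               rb$n_supporting_snps[si]))
  }
  if (!length(out)) return(empty_intervals())
  res <- do.call(rbind, out)
  res <- res[order(res$chrom, res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Interval width in megabases
#'
#' `(end - start) / 1e6`: the end-minus-start convention matches how a
#' physical interval quoted by its flanking SNP coordinates is reported
#' (e.g. 59,315,357-76,806,837 bp is a 17.49 Mb interval). Full precision is
#' kept internally; round only at report time.
#'
#' @param interval data.frame with `start` and `end` (or a one-row slice).
#' @return numeric width(s) in Mb.
#' @examples
#' interval_width_mb(data.frame(start = 59315357, end = 76806837))
#' @export
interval_width_mb <- function(interval) {
  stopifnot(all(interval$end >= interval$start))
  (interval$end - interval$start) / 1e6
}

#' Export intervals as BED (0-based half-open) and TSV
#'
#' @param intervals interval data.frame.
#' @param bed_path,tsv_path output files (either may be `NULL`).
#' @export
write_intervals <- function(intervals, bed_path = NULL, tsv_path = NULL) {
  if (!is.null(bed_path)) {
    bed <- data.frame(chrom = intervals$chrom,
                      start = intervals$start - 1,  # 0-based half-open
                      end = intervals$end,
                      name = intervals$method)
    write.table(bed, bed_path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  }
  if (!is.null(tsv_path)) {
    out <- intervals
    out$width_mb <- interval_width_mb(intervals)
    write.table(out, tsv_path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(intervals)
}
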