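#' Call narrow peaks with a local-Poisson window test
#'
#' A documented substitute for a full peak caller: the genome is tiled in
#' non-overlapping windows, each window's fragment count is tested against a
#' Poisson expectation `lambda = max(genome-wide, 1 kb local, 10 kb local)`
#' (the local lambdas are running means of window counts over the flanking
#' span), p-values are BH-adjusted over all tested windows, significant
#' adjacent windows are joined, the summit is the bp of maximum fragment
#' coverage within the joined region, and the region's score is
#' `-log10` of its minimum window q-value.
#'
#' @param fs A `FragmentSet` or `GRanges` of fragments.
#' @param layout `Seqinfo` layout.
#' @param window Window size in bp.
#' @param local_lambda_windows Spans (bp) for local background estimation.
#' @param q_threshold BH q-value cutoff for a window to be significant.
#' @return A `GRanges` of peaks with metadata `summit` (bp, 1-based) and
#'   `neglog10_q`; `metadata(x)$provenance == "called"`.
#' @export
call_peaks_poisson <- function(fs, layout, window = 150,
                               local_lambda_windows = c(1000, 10000),
                               q_threshold = 0.05) {
  gr <- as_fragments(fs)
  empty <- GenomicRanges::GRanges(seqinfo = layout)
  empty$summit <- integer(0)
  empty$neglog10_q <- numeric(0)
  S4Vectors::metadata(empty)$provenance <- "called"
  if (length(gr) == 0) return(empty)

  lens <- GenomeInfoDb::seqlengths(layout)
  chroms <- GenomeInfoDb::seqnames(layout)
  win_list <- list()
  cnt_list <- list()
  for (ch in chroms) {
    n_bins <- ceiling(lens[[ch]] / window)
    bins <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = (seq_len(n_bins) - 1) * window + 1,
                           end = pmin(seq_len(n_bins) * window, lens[[ch]])))
    win_list[[ch]] <- bins
    cnt_list[[ch]] <- GenomicRanges::countOverlaps(bins, gr,
                                                   ignore.strand = TRUE)
  }
  all_counts <- unlist(cnt_list, use.names = FALSE)
  lambda_bg <- mean(all_counts)

  pvals <- lapply(chroms, function(ch) {
    cnt <- cnt_list[[ch]]
    # mask clearly enriched windows out of the local background estimate so
    # a peak does not inflate its own lambda
    enriched <- stats::ppois(cnt - 1, lambda_bg, lower.tail = FALSE) < 0.01
    bg_cnt <- ifelse(enriched, lambda_bg, as.numeric(cnt))
    lam <- rep(lambda_bg, length(cnt))
    for (span in local_lambda_windows) {
      k <- max(1L, round(span / window))
      if (k %% 2 == 0) k <- k + 1L
      loc <- stats::filter(bg_cnt, rep(1 / k, k), sides = 2)
      loc[is.na(loc)] <- lambda_bg
      lam <- pmax(lam, as.numeric(loc))
    }
    stats::ppois(cnt - 1, lam, lower.tail = FALSE)
  })
  names(pvals) <- chroms
  q_all <- stats::p.adjust(unlist(pvals, use.names = FALSE), method = "BH")
  qvals <- split(q_all, rep(chroms, times = lengths(pvals)))
  qvals <- qvals[chroms]

  cov <- GenomicRanges::coverage(gr)
  peaks <- GenomicRanges::GRanges()
  for (ch in chroms) {
    sig <- which(qvals[[ch]] < q_threshold)
    if (!length(sig)) next
    sig_w <- win_list[[ch]][sig]
    joined <- GenomicRanges::reduce(sig_w)
    hit <- GenomicRanges::findOverlaps(joined, sig_w)
    min_q <- vapply(split(qvals[[ch]][sig][S4Vectors::subjectHits(hit)],
                          S4Vectors::queryHits(hit)), min, numeric(1))
    summit <- integer(length(joined))
    ch_cov <- cov[[ch]]
    for (i in seq_along(joined)) {
      v <- IRanges::Views(ch_cov, GenomicRanges::start(joined)[i],
                          min(GenomicRanges::end(joined)[i], length(ch_cov)))
      summit[i] <- GenomicRanges::start(joined)[i] +
        which.max(as.numeric(v[[1]])) - 1L
    }
    joined$summit <- summit
    joined$neglog10_q <- -log10(pmax(min_q, 1e-320))
    peaks <- concat_gr(list(peaks, joined))
  }
  peaks <- set_layout(sort(peaks), layout)
  S4Vectors::metadata(peaks)$provenance <- "called"
  peaks
}

#' Keep only high-confidence peaks
#'
#' Retains peaks with `-log10(q)` strictly greater than the threshold
#' (default 100).
#'
#' @param peaks A peak `GRanges` with `neglog10_q`.
#' @param min_neglog10_q Strict lower bound.
#' @return Filtered `GRanges`.
#' @export
filter_high_confidence <- function(peaks, min_neglog10_q = 100) {
  if (length(peaks) == 0) return(peaks)
  peaks[peaks$neglog10_q > min_neglog10_q]
}

#' Merge peaks across replicates
#'
#' Union of both replicates' intervals merged at gap 0 (bookended intervals
#' join). A merged peak takes the maximum constituent score and the summit of
#' its highest-scoring constituent.
#'
#' @param p1,p2 Peak `GRanges` with `summit` and `neglog10_q`.
#' @return Merged peak `GRanges`, `provenance == "merged"`.
#' @export
merge_replicate_peaks <- function(p1, p2) {
  all_p <- c(p1, p2)
  if (length(all_p) == 0) {
    S4Vectors::metadata(all_p)$provenance <- "merged"
    return(all_p)
  }
  merged <- GenomicRanges::reduce(GenomicRanges::granges(all_p),
                                  ignore.strand = TRUE)
  hit <- GenomicRanges::findOverlaps(merged, all_p, ignore.strand = TRUE)
  q_by <- split(all_p$neglog10_q[S4Vectors::subjectHits(hit)],
                S4Vectors::queryHits(hit))
  s_by <- split(all_p$summit[S4Vectors::subjectHits(hit)],
                S4Vectors::queryHits(hit))
  merged$summit <- vapply(seq_along(merged), function(i) {
    b <- as.character(i)
    as.integer(s_by[[b]][which.max(q_by[[b]])])
  }, integer(1))
  merged$neglog10_q <- unname(vapply(as.character(seq_along(merged)),
                                     function(b) max(q_by[[b]]), numeric(1)))
  merged <- sort(merged)
  S4Vectors::metadata(merged)$provenance <- "merged"
  merged
}

#' Build a heterochromatin blacklist
#'
#' High-confidence H3K9me3 peaks (`-log10(q) > 100`) merged at gap 3000 bp,
#' unioned with any extra regions (e.g. a curated high-signal/low-mappability
#' list).
#'
#' @param h3k9me3_peaks Peak `GRanges` with `neglog10_q`.
#' @param extra_regions Optional `GRanges` of additional blacklist regions.
#' @param min_neglog10_q Confidence threshold (strict).
#' @param merge_gap Merge distance in bp.
#' @return A disjoint `GRanges`, `provenance == "blacklist"`.
#' @export
build_blacklist <- function(h3k9me3_peaks, extra_regions = NULL,
                            min_neglog10_q = 100, merge_gap = 3000) {
  hc <- filter_high_confidence(h3k9me3_peaks, min_neglog10_q)
  merged <- merge_intervals(hc, max_gap = merge_gap)
  if (!is.null(extra_regions) && length(extra_regions)) {
    merged <- GenomicRanges::reduce(
      concat_gr(list(merged, GenomicRanges::granges(extra_regions))),
      ignore.strand = TRUE)
  }
  S4Vectors::metadata(merged)$provenance <- "blacklist"
  merged
}

#' Remove blacklisted peaks
#'
#' Drops any peak overlapping a blacklist region by >= 1 bp.
#'
#' @param peaks Peak `GRanges`.
#' @param blacklist Blacklist `GRanges`.
#' @return Filtered `GRanges`.
#' @export
apply_blacklist <- function(peaks, blacklist) {
  if (length(peaks) == 0 || length(blacklist) == 0) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, blacklist, ignore.strand = TRUE)]
}

#' Shuffle a peak set to matched random regions
#'
#' Places the same number of regions with the identical multiset of lengths
#' (hence the same total bp) uniformly over the genome, outside any excluded
#' regions, without overlap among the shuffled regions; chromosome
#' reassignment is allowed. Deterministic for a given seed.
#'
#' @param peaks Peak `GRanges` to mimic.
#' @param layout `Seqinfo` layout.
#' @param exclude_regions Optional `GRanges` the shuffled regions must avoid.
#' @param seed Integer seed.
#' @param max_tries Placement retries per region before failing.
#' @return A `GRanges` of shuffled regions, `provenance == "shuffled"`.
#' @export
shuffle_peaks <- function(peaks, layout, exclude_regions = NULL, seed = 1L,
                          max_tries = 1000) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  widths <- GenomicRanges::width(peaks)
  out <- place_nonoverlapping(length(peaks), widths, layout,
                              avoid = exclude_regions, min_gap = 0,
                              max_tries = max_tries)
  S4Vectors::metadata(out)$provenance <- "shuffled"
  out
}
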