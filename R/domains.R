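#' Call broad enrichment islands
#'
#' SICER-style island calling for broad histone marks. The genome is tiled
#' in `w`-bp windows; the expected count per window is
#' `lambda = total_fragments * w / (egf * genome_length)` (egf = effective
#' genome fraction). A window is eligible iff its fragment count reaches the
#' smallest integer whose Poisson upper-tail probability falls below
#' `window_p`. Eligible windows within `gap` bp of each other cluster into
#' one island, scored as the sum over eligible windows of
#' `-ln P(count; lambda)` (Poisson surprisal, in nats); the island interval
#' spans its first to last eligible window. Fragments are counted at their
#' full extent with >= 1 bp overlap (no shift).
#'
#' @param fs `FragmentSet` or `GRanges` of fragments.
#' @param layout `Seqinfo` layout.
#' @param w Window size in bp (default 500).
#' @param gap Maximum gap in bp between eligible windows of one island
#'   (default 2000).
#' @param egf Effective genome fraction (default 0.7).
#' @param window_p Window eligibility tail probability (default 0.2).
#' @return `GRanges` of islands with `score` (nats) and
#'   `n_eligible_windows`.
#' @export
call_islands <- function(fs, layout, w = 500, gap = 2000, egf = 0.7,
                         window_p = 0.2) {
  gr <- as_fragments(fs)
  if (length(gr) == 0) stop("cannot call islands on an empty fragment set")
  lens <- GenomeInfoDb::seqlengths(layout)
  genome_len <- sum(as.numeric(lens))
  lambda <- length(gr) * w / (egf * genome_len)
  if (lambda <= 0) stop("expected window count is zero")
  # smallest count whose upper-tail Poisson probability < window_p
  min_count <- stats::qpois(window_p, lambda, lower.tail = FALSE) + 1
  while (stats::ppois(min_count - 1, lambda, lower.tail = FALSE) >= window_p) {
    min_count <- min_count + 1
  }

  islands <- GenomicRanges::GRanges()
  for (ch in GenomeInfoDb::seqnames(layout)) {
    L <- lens[[ch]]
    n_bins <- ceiling(L / w)
    bins <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = (seq_len(n_bins) - 1) * w + 1,
                           end = pmin(seq_len(n_bins) * w, L)))
    cnt <- GenomicRanges::countOverlaps(bins, gr, ignore.strand = TRUE)
    elig <- which(cnt >= min_count)
    if (!length(elig)) next
    ew <- bins[elig]
    score_w <- -stats::dpois(cnt[elig], lambda, log = TRUE)
    isl <- merge_intervals(ew, max_gap = gap)
    hit <- GenomicRanges::findOverlaps(isl, ew)
    isl$score <- as.numeric(
      vapply(split(score_w[S4Vectors::subjectHits(hit)],
                   S4Vectors::queryHits(hit)), sum, numeric(1)))
    isl$n_eligible_windows <- as.integer(
      vapply(split(S4Vectors::subjectHits(hit),
                   S4Vectors::queryHits(hit)), length, integer(1)))
    islands <- concat_gr(list(islands, isl))
  }
  set_layout(sort(islands), layout)
}

#' Filter islands to broad domains
#'
#' Keeps islands with score strictly greater than `min_score` and length
#' strictly greater than `min_length` bp (the Polycomb-domain filters).
#'
#' @param islands Output of [call_islands()].
#' @param min_score Score threshold (strict, default 500).
#' @param min_length Length threshold in bp (strict, default 3000).
#' @return Filtered `GRanges`.
#' @export
filter_domains <- function(islands, min_score = 500, min_length = 3000) {
  if (length(islands) == 0) return(islands)
  islands[islands$score > min_score &
            GenomicRanges::width(islands) > min_length]
}

#' Merge domains across replicates
#'
#' Union of both replicates' domains merged at gaps up to `max_gap` bp
#' (default 10 kb); a merged domain's score is the sum of its constituents.
#'
#' @param domains_rep1,domains_rep2 Domain `GRanges` with `score`.
#' @param max_gap Merge distance in bp.
#' @return Merged domain `GRanges`.
#' @export
merge_domains <- function(domains_rep1, domains_rep2, max_gap = 10000) {
  all_d <- c(domains_rep1, domains_rep2)
  if (length(all_d) == 0) return(all_d)
  merged <- merge_intervals(all_d, max_gap = max_gap)
  hit <- GenomicRanges::findOverlaps(merged, all_d, ignore.strand = TRUE,
                                     maxgap = 0)
  sc <- if (!is.null(all_d$score)) all_d$score else rep(0, length(all_d))
  merged$score <- as.numeric(
    vapply(split(sc[S4Vectors::subjectHits(hit)],
                 S4Vectors::queryHits(hit)), sum, numeric(1)))
  merged
}

#' Per-region fragment coverage
#'
#' Counts each replicate's fragments in each region, divides by region
#' length, and averages across replicates: `reads` is the mean count,
#' `coverage = reads / length`. The default `"overlap"` mode counts a
#' fragment in every region it overlaps by >= 1 bp (the featureCounts
#' convention); `"midpoint"` assigns each fragment to at most one region,
#' which removes the fragment-length edge inflation that otherwise biases
#' narrow-region coverage upward relative to broad regions.
#'
#' @param frag_sets List of `FragmentSet`s (replicates of one condition).
#' @param regions `GRanges` of regions.
#' @param mode `"overlap"` or `"midpoint"`.
#' @return data.frame with `chrom`, `start`, `end`, `length`, `reads`,
#'   `coverage`.
#' @export
region_coverage <- function(frag_sets, regions,
                            mode = c("overlap", "midpoint")) {
  mode <- match.arg(mode)
  stopifnot(length(frag_sets) >= 1)
  cnt <- vapply(frag_sets, function(fs) {
    gr <- as_fragments(fs)
    if (mode == "midpoint" && length(gr)) {
      mid <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
      gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                   IRanges::IRanges(mid, width = 1))
    }
    count_in_regions(gr, regions)
  }, integer(length(regions)))
  if (is.null(dim(cnt))) cnt <- matrix(cnt, ncol = length(frag_sets))
  reads <- rowMeans(cnt)
  len <- GenomicRanges::width(regions)
  data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
             start = GenomicRanges::start(regions),
             end = GenomicRanges::end(regions),
             length = len, reads = reads, coverage = reads / len,
             stringsAsFactors = FALSE)
}

#' Peaks outside domains
#'
#' Removes peaks that overlap any domain by >= 1 bp, the preparation step
#' for the peak-vs-domain coverage comparison.
#'
#' @param peaks Peak `GRanges`.
#' @param domains Domain `GRanges`.
#' @return Filtered `GRanges`.
#' @export
peaks_outside_domains <- function(peaks, domains) {
  if (length(domains) == 0) return(peaks)
  peaks[!IRanges::overlapsAny(peaks, domains, ignore.strand = TRUE)]
}

#' Domain-to-peak coverage ratio
#'
#' Ratio of mean per-bp coverage in broad domains to mean per-bp coverage in
#' narrow peaks (peaks must already exclude those inside domains, see
#' [peaks_outside_domains()]). A ratio of 3 means peaks carry 3-fold less
#' mark coverage than domains.
#'
#' @param peak_coverage,domain_coverage Outputs of [region_coverage()].
#' @return list with `ratio`, `mean_peak`, `mean_domain`.
#' @export
coverage_ratio <- function(peak_coverage, domain_coverage) {
  if (nrow(peak_coverage) == 0) stop("no peaks left after domain exclusion")
  if (nrow(domain_coverage) == 0) stop("empty domain set")
  mp <- mean(peak_coverage$coverage)
  md <- mean(domain_coverage$coverage)
  if (mp <= 0) stop("zero mean peak coverage")
  list(ratio = md / mp, mean_peak = mp, mean_domain = md)
}
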