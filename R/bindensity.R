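#' Tile the genome in fixed-width bins
#'
#' One bin grid per chromosome; the terminal bin may be short and is flagged
#' (`full_width = FALSE`).
#'
#' @param layout `Seqinfo` layout.
#' @param width Bin width in bp (default 500).
#' @return `GRanges` of bins with a `full_width` flag.
#' @export
make_bins <- function(layout, width = 500) {
  stopifnot(width >= 1)
  lens <- GenomeInfoDb::seqlengths(layout)
  bins <- GenomicRanges::GRanges()
  for (ch in GenomeInfoDb::seqnames(layout)) {
    n_bins <- ceiling(lens[[ch]] / width)
    b <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = (seq_len(n_bins) - 1) * width + 1,
                           end = pmin(seq_len(n_bins) * width, lens[[ch]])))
    bins <- concat_gr(list(bins, b))
  }
  bins$full_width <- GenomicRanges::width(bins) == width
  set_layout(bins, layout)
}

#' Depth-matched per-bin read density by peak-binding stratum
#'
#' Counts each condition's (already depth-matched) fragments per bin and
#' stratifies bins by whether they overlap a reference peak (>= 1 bp). With
#' the default `"midpoint"` rule each fragment lands in exactly one bin
#' (the one containing its midpoint), so per-condition totals equal the
#' subsampled depth exactly; `"overlap"` counts a fragment in every bin it
#' touches. Short terminal bins are kept in the table but excluded from the
#' per-stratum summaries.
#'
#' @param frag_by_condition Named list (one `FragmentSet` per condition),
#'   all of identical size (subsample first, see [subsample_fragments()]).
#' @param bins Output of [make_bins()].
#' @param reference_peaks `GRanges` of reference peaks.
#' @param mode `"midpoint"` (conserving) or `"overlap"`.
#' @return list with `table` (data.frame: bin coordinates, `bound`,
#'   `full_width`, one count column per condition) and `summary`
#'   (data.frame: per condition x stratum mean, quantiles, n_bins).
#' @export
bin_density <- function(frag_by_condition, bins, reference_peaks,
                        mode = c("midpoint", "overlap")) {
  mode <- match.arg(mode)
  stopifnot(length(frag_by_condition) >= 1)
  sizes <- vapply(frag_by_condition, function(fs) length(as_fragments(fs)),
                  integer(1))
  if (length(unique(sizes)) > 1) {
    stop("conditions must be subsampled to equal fragment counts (got ",
         paste(sizes, collapse = ", "), ")")
  }
  counts <- lapply(frag_by_condition, function(fs) {
    gr <- as_fragments(fs)
    if (mode == "midpoint" && length(gr)) {
      mid <- floor((GenomicRanges::start(gr) + GenomicRanges::end(gr)) / 2)
      gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(gr),
                                   IRanges::IRanges(mid, width = 1))
    }
    GenomicRanges::countOverlaps(bins, gr, ignore.strand = TRUE)
  })
  bound <- IRanges::overlapsAny(bins, reference_peaks, ignore.strand = TRUE)
  tab <- data.frame(chrom = as.character(GenomicRanges::seqnames(bins)),
                    start = GenomicRanges::start(bins),
                    end = GenomicRanges::end(bins),
                    bound = bound,
                    full_width = bins$full_width,
                    stringsAsFactors = FALSE)
  for (nm in names(counts)) tab[[paste0("count_", nm)]] <- counts[[nm]]

  qs <- c(0.25, 0.5, 0.75)
  rows <- list()
  for (nm in names(counts)) {
    for (stratum in c("bound", "unbound")) {
      keep <- bins$full_width & (if (stratum == "bound") bound else !bound)
      v <- counts[[nm]][keep]
      rows[[paste(nm, stratum)]] <- data.frame(
        condition = nm, stratum = stratum, n_bins = sum(keep),
        mean = if (length(v)) mean(v) else NA_real_,
        q25 = if (length(v)) stats::quantile(v, qs[1], names = FALSE) else NA,
        median = if (length(v)) stats::quantile(v, qs[2], names = FALSE) else NA,
        q75 = if (length(v)) stats::quantile(v, qs[3], names = FALSE) else NA,
        stringsAsFactors = FALSE)
    }
  }
  list(table = tab, summary = do.call(rbind, c(rows, make.row.names = FALSE)))
}
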