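#' Binned coverage track
#'
#' A per-chromosome array of values over a fixed-width bin grid, tagged with
#' its normalization state. Valid state transitions are raw -> rpkm,
#' raw -> scaled, and (raw|rpkm|scaled) -> zscore.
#'
#' @param values Named list (by chromosome) of numeric vectors.
#' @param layout `Seqinfo` layout.
#' @param bin_size Bin width in bp.
#' @param state One of `"raw"`, `"rpkm"`, `"scaled"`, `"zscore"`.
#' @return An object of class `BinnedTrack`.
#' @export
binned_track <- function(values, layout, bin_size,
                         state = c("raw", "rpkm", "scaled", "zscore")) {
  state <- match.arg(state)
  lens <- GenomeInfoDb::seqlengths(layout)
  chroms <- GenomeInfoDb::seqnames(layout)
  stopifnot(setequal(names(values), chroms))
  for (ch in chroms) {
    expect_n <- ceiling(lens[[ch]] / bin_size)
    if (length(values[[ch]]) != expect_n) {
      stop(sprintf("chromosome %s: %d bins supplied, %d expected",
                   ch, length(values[[ch]]), expect_n))
    }
  }
  if (state == "raw" && any(unlist(values, use.names = FALSE) < 0)) {
    stop("raw track values must be >= 0")
  }
  structure(list(values = values[chroms], layout = layout,
                 bin_size = bin_size, state = state),
            class = "BinnedTrack")
}

#' @export
print.BinnedTrack <- function(x, ...) {
  cat(sprintf("BinnedTrack: %d chromosome(s), bin %d bp, state '%s'\n",
              length(x$values), x$bin_size, x$state))
  invisible(x)
}

# All bin values of a track as one numeric vector (genome-wide order).
track_values <- function(track) unlist(track$values, use.names = FALSE)

#' Compute binned fragment coverage
#'
#' Each fragment adds 1 to every bin it overlaps by >= 1 bp. Fragments at or
#' above `max_fragment_length` bp can be excluded (the sub-nucleosomal filter
#' applied to transcription-factor tracks) and exact duplicates (identical
#' chrom/start/end) collapsed to one.
#'
#' @param fs A `FragmentSet` or `GRanges`.
#' @param layout `Seqinfo` layout.
#' @param bin_size Bin width in bp (>= 1).
#' @param max_fragment_length Exclusive length cutoff, or `NULL` for none.
#' @param dedup Collapse exact-duplicate fragments to a single count.
#' @return A raw-state [binned_track()].
#' @export
compute_coverage <- function(fs, layout, bin_size,
                             max_fragment_length = NULL, dedup = FALSE) {
  stopifnot(bin_size >= 1)
  gr <- as_fragments(fs)
  if (!is.null(max_fragment_length)) {
    gr <- gr[GenomicRanges::width(gr) < max_fragment_length]
  }
  if (dedup) gr <- unique(GenomicRanges::granges(gr))
  lens <- GenomeInfoDb::seqlengths(layout)
  chroms <- GenomeInfoDb::seqnames(layout)
  vals <- lapply(chroms, function(ch) {
    n_bins <- ceiling(lens[[ch]] / bin_size)
    bins <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = (seq_len(n_bins) - 1) * bin_size + 1,
                           end = pmin(seq_len(n_bins) * bin_size, lens[[ch]])))
    as.numeric(GenomicRanges::countOverlaps(bins, gr, ignore.strand = TRUE))
  })
  names(vals) <- chroms
  binned_track(vals, layout, bin_size, "raw")
}

#' RPKM-normalize a track
#'
#' Reads per kilobase of bin per million fragments:
#' `value * 1e9 / (bin_size * total_fragments)`.
#'
#' @param track A raw-state `BinnedTrack`.
#' @param total_fragments Library size (> 0).
#' @return An rpkm-state `BinnedTrack`.
#' @export
to_rpkm <- function(track, total_fragments) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$state != "raw") stop("RPKM normalization requires a raw track")
  if (total_fragments <= 0) stop("total_fragments must be > 0")
  f <- 1e9 / (track$bin_size * total_fragments)
  track$values <- lapply(track$values, function(v) v * f)
  track$state <- "rpkm"
  track
}

#' Scale a raw track by a normalization factor
#'
#' Multiplies every bin by `scale` (typically the output of
#' [final_scale_factor()]) and tags the track `scaled`.
#'
#' @param track A raw-state `BinnedTrack`.
#' @param scale Positive multiplicative factor.
#' @return A scaled-state `BinnedTrack`.
#' @export
scale_track <- function(track, scale) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$state != "raw") stop("scaling requires a raw track")
  if (scale <= 0) stop("scale must be > 0")
  track$values <- lapply(track$values, function(v) v * scale)
  track$state <- "scaled"
  track
}

#' Merge replicate tracks
#'
#' Per-bin arithmetic mean of tracks on an identical grid and in the same
#' normalization state.
#'
#' @param tracks List of `BinnedTrack`s.
#' @return A `BinnedTrack` of per-bin means.
#' @export
merge_replicates <- function(tracks) {
  stopifnot(length(tracks) >= 1)
  t1 <- tracks[[1]]
  for (t in tracks[-1]) {
    if (t$bin_size != t1$bin_size || t$state != t1$state ||
        !identical(lengths(t$values), lengths(t1$values)) ||
        !identical(names(t$values), names(t1$values))) {
      stop("tracks must share layout, bin size and state to be merged")
    }
  }
  out <- t1
  for (ch in names(out$values)) {
    m <- rowMeans(vapply(tracks, function(t) t$values[[ch]],
                         numeric(length(t1$values[[ch]]))))
    out$values[[ch]] <- m
  }
  out
}

#' Z-score normalize a track
#'
#' Subtracts the genome-wide mean and divides by the genome-wide population
#' standard deviation, computed over all bins of all chromosomes. If the
#' track is constant (sd 0), the output is all zeros with a warning.
#'
#' @param track A `BinnedTrack` in any non-zscore state.
#' @return A zscore-state `BinnedTrack` (mean 0, sd 1 within 1e-9).
#' @export
zscore_normalize <- function(track) {
  stopifnot(inherits(track, "BinnedTrack"))
  if (track$state == "zscore") return(track)
  v <- track_values(track)
  m <- mean(v)
  s <- sqrt(mean((v - m)^2))  # population sd
  if (s == 0) {
    warning("track has zero variance; z-score output is all zeros")
    track$values <- lapply(track$values, function(x) x * 0)
  } else {
    track$values <- lapply(track$values, function(x) (x - m) / s)
  }
  track$state <- "zscore"
  track
}

#' Count fragments in regions
#'
#' A fragment is counted for every region it overlaps by >= 1 bp (the
#' featureCounts/bedtools any-overlap convention), so a fragment spanning two
#' regions contributes to both.
#'
#' @param fs A `FragmentSet` or `GRanges` of fragments.
#' @param regions `GRanges` of regions.
#' @return Integer vector of per-region counts, parallel to `regions`.
#' @export
count_in_regions <- function(fs, regions) {
  gr <- as_fragments(fs)
  GenomicRanges::countOverlaps(regions, gr, ignore.strand = TRUE)
}

#' Build a reads-in-peaks count matrix
#'
#' One row per region, one column per sample; used as input to
#' [tmm_factors()].
#'
#' @param frag_sets Named list of `FragmentSet`s.
#' @param regions `GRanges` of peak regions.
#' @return Integer matrix regions x samples.
#' @export
count_matrix <- function(frag_sets, regions) {
  m <- vapply(frag_sets, function(fs) count_in_regions(fs, regions),
              integer(length(regions)))
  if (is.null(dim(m))) m <- matrix(m, ncol = length(frag_sets))
  colnames(m) <- names(frag_sets)
  m
}

#' Write a track as bedGraph
#'
#' One line per run of equal-valued bins; zero-valued runs are skipped unless
#' `dense = TRUE`. Coordinates are 0-based half-open.
#'
#' @param track A `BinnedTrack`.
#' @param path Output path.
#' @param dense Also write zero bins.
#' @export
write_bedgraph <- function(track, path, dense = FALSE) {
  lens <- GenomeInfoDb::seqlengths(track$layout)
  con <- file(path, "w")
  on.exit(close(con))
  for (ch in names(track$values)) {
    v <- track$values[[ch]]
    r <- rle(v)
    ends_idx <- cumsum(r$lengths)
    starts_idx <- ends_idx - r$lengths + 1
    start0 <- (starts_idx - 1) * track$bin_size
    end0 <- pmin(ends_idx * track$bin_size, lens[[ch]])
    keep <- if (dense) rep(TRUE, length(r$values)) else r$values != 0
    if (any(keep)) {
      writeLines(paste(ch, format(start0[keep], scientific = FALSE, trim = TRUE),
                       format(end0[keep], scientific = FALSE, trim = TRUE),
                       format(r$values[keep], scientific = FALSE, trim = TRUE),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}
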