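#' Construct a genome layout
#'
#' A genome layout is the set of chromosome names and lengths that every
#' interval, bin grid and fragment set in the package is validated against.
#' It is represented as a [GenomeInfoDb::Seqinfo] object.
#'
#' @param chroms Character vector of unique chromosome names.
#' @param lengths Integer vector of chromosome lengths in bp (> 0).
#' @return A `Seqinfo` object.
#' @examples
#' genome_layout(c("chr1", "chr2"), c(2.5e6, 2.5e6))
#' @export
genome_layout <- function(chroms, lengths) {
  chroms <- as.character(chroms)
  lengths <- as.numeric(lengths)
  if (length(chroms) != length(lengths)) {
    stop("chroms and lengths must have the same length")
  }
  if (anyDuplicated(chroms)) stop("chromosome names must be unique")
  if (any(!is.finite(lengths)) || any(lengths <= 0)) {
    stop("chromosome lengths must be positive")
  }
  GenomeInfoDb::Seqinfo(seqnames = chroms, seqlengths = as.integer(lengths))
}

#' Read a chromosome-sizes file
#'
#' Two tab-separated columns: chromosome name, length in bp.
#'
#' @param path File path.
#' @return A `Seqinfo` layout.
#' @export
read_chrom_sizes <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           stringsAsFactors = FALSE,
                           col.names = c("chrom", "length"))
  genome_layout(tab$chrom, tab$length)
}

#' Write a chromosome-sizes file
#'
#' @param layout A `Seqinfo` layout.
#' @param path Output path.
#' @export
write_chrom_sizes <- function(layout, path) {
  tab <- data.frame(chrom = GenomeInfoDb::seqnames(layout),
                    length = GenomeInfoDb::seqlengths(layout))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Validate a GRanges object against a layout: known chromosomes, positive
# widths, and no interval crossing a chromosome end (rejected, not clipped).
validate_intervals <- function(gr, layout = NULL, what = "interval") {
  if (any(GenomicRanges::width(gr) < 1)) {
    stop(sprintf("%s with zero or negative width", what))
  }
  if (!is.null(layout)) {
    chroms <- as.character(GenomeInfoDb::seqnames(layout))
    bad <- !(as.character(GenomicRanges::seqnames(gr)) %in% chroms)
    if (any(bad)) {
      stop(sprintf("%s on unknown chromosome: %s", what,
                   paste(unique(as.character(GenomicRanges::seqnames(gr))[bad]),
                         collapse = ", ")))
    }
    lens <- GenomeInfoDb::seqlengths(layout)
    ends <- GenomicRanges::end(gr)
    lim <- lens[as.character(GenomicRanges::seqnames(gr))]
    if (any(ends > lim) || any(GenomicRanges::start(gr) < 1)) {
      stop(sprintf("%s extends beyond chromosome bounds", what))
    }
  }
  invisible(gr)
}

# Concatenate GRanges built per chromosome (their seqlevels differ by
# construction; the benign level-merge warning is silenced).
concat_gr <- function(grl) {
  if (!length(grl)) return(GenomicRanges::GRanges())
  suppressWarnings(do.call(c, unname(grl)))
}

# Attach a layout's Seqinfo to a GRanges (keeps only levels in use plus
# layout levels so downstream tiling sees the full genome).
set_layout <- function(gr, layout) {
  GenomeInfoDb::seqlevels(gr) <- GenomeInfoDb::seqnames(layout)
  suppressWarnings(GenomeInfoDb::seqinfo(gr) <- layout)
  gr
}

#' Read a BED file
#'
#' Reads 3-6 column BED (tab-separated, 0-based half-open) into a `GRanges`
#' (1-based closed, the in-memory convention; conversion happens only at the
#' file boundary). Columns 4-6 populate `name`, `score` and strand when
#' present. Input order is preserved.
#'
#' @param path File path.
#' @param layout Optional `Seqinfo`; intervals are validated against it.
#' @return A `GRanges`.
#' @export
read_bed <- function(path, layout = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    gr <- GenomicRanges::GRanges()
    if (!is.null(layout)) gr <- set_layout(gr, layout)
    return(gr)
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stop(sprintf("malformed BED line %d: fewer than 3 fields",
                 which(nf < 3)[1]))
  }
  chrom <- vapply(fields, `[[`, "", 1L)
  start0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 2L)))
  end0 <- suppressWarnings(as.numeric(vapply(fields, `[[`, "", 3L)))
  bad <- !is.finite(start0) | !is.finite(end0)
  if (any(bad)) {
    stop(sprintf("malformed BED line %d: non-numeric coordinates",
                 which(bad)[1]))
  }
  if (any(start0 < 0)) {
    stop(sprintf("invalid BED line %d: negative start", which(start0 < 0)[1]))
  }
  if (any(start0 >= end0)) {
    stop(sprintf("invalid BED line %d: start >= end (empty interval)",
                 which(start0 >= end0)[1]))
  }
  name <- ifelse(nf >= 4, vapply(fields, function(f) f[min(4L, length(f))], ""), NA)
  name[nf < 4] <- NA_character_
  score <- rep(NA_real_, length(fields))
  has5 <- nf >= 5
  score[has5] <- suppressWarnings(
    as.numeric(vapply(fields[has5], `[[`, "", 5L)))
  strand <- rep("*", length(fields))
  has6 <- nf >= 6
  strand[has6] <- vapply(fields[has6], `[[`, "", 6L)
  strand[!strand %in% c("+", "-")] <- "*"
  gr <- GenomicRanges::GRanges(
    seqnames = chrom,
    ranges = IRanges::IRanges(start = start0 + 1, end = end0),
    strand = strand)
  if (any(!is.na(name))) gr$name <- name
  if (any(!is.na(score))) gr$score <- score
  if (!is.null(layout)) {
    validate_intervals(gr, layout, what = "BED interval")
    gr <- set_layout(gr, layout)
  }
  gr
}

#' Write a BED file
#'
#' Writes `GRanges` as tab-separated BED, 0-based half-open. Emits BED3 when
#' neither `name` nor `score` metadata is present, BED6 otherwise (missing
#' names become ".", missing scores 0, unknown strand "."). Round-trips with
#' [read_bed()]: coordinates and scores are preserved bit-exactly.
#'
#' @param gr A `GRanges`.
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  if (length(gr) == 0) {
    file.create(path)
    return(invisible(path))
  }
  validate_intervals(gr, what = "interval")
  chrom <- as.character(GenomicRanges::seqnames(gr))
  start0 <- format(GenomicRanges::start(gr) - 1, scientific = FALSE, trim = TRUE)
  end0 <- format(GenomicRanges::end(gr), scientific = FALSE, trim = TRUE)
  has_meta <- any(c("name", "score") %in% names(S4Vectors::mcols(gr)))
  if (!has_meta) {
    lines <- paste(chrom, start0, end0, sep = "\t")
  } else {
    name <- if ("name" %in% names(S4Vectors::mcols(gr))) gr$name else NA
    name <- ifelse(is.na(name), ".", name)
    score <- if ("score" %in% names(S4Vectors::mcols(gr))) gr$score else NA
    score <- ifelse(is.na(score), "0",
                    format(score, scientific = FALSE, trim = TRUE, digits = 17))
    strand <- as.character(GenomicRanges::strand(gr))
    strand[strand == "*"] <- "."
    lines <- paste(chrom, start0, end0, name, score, strand, sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read gene annotation
#'
#' Reads gene models from GFF3 (via \pkg{rtracklayer}; records with
#' `type == "gene"`) or stranded BED6 (column 4 = gene id). The transcription
#' start site (TSS) is the 5' end of the gene body: `start` for + strand,
#' `end` for - strand.
#'
#' @param path File path.
#' @param format `"gff3"` or `"bed"`.
#' @param layout Optional `Seqinfo` for validation.
#' @return A `GRanges` with metadata columns `gene_id` and `tss` (1-based
#'   position).
#' @export
read_gene_annotation <- function(path, format = c("gff3", "bed"),
                                 layout = NULL) {
  format <- match.arg(format)
  if (format == "gff3") {
    gff <- rtracklayer::import(path, format = "gff3")
    genes <- gff[gff$type == "gene"]
    ids <- genes$ID
    if (is.null(ids)) ids <- genes$gene_id
    if (is.null(ids) || anyNA(ids)) stop("GFF3 gene records must carry an ID")
    gr <- GenomicRanges::granges(genes)
    gr$gene_id <- as.character(ids)
  } else {
    gr <- read_bed(path, layout = layout)
    if (is.null(gr$name)) stop("BED gene annotation needs a name column")
    gr$gene_id <- gr$name
    gr$name <- NULL
    gr$score <- NULL
  }
  st <- as.character(GenomicRanges::strand(gr))
  if (any(st == "*")) stop("gene records must be stranded")
  if (anyDuplicated(gr$gene_id)) {
    stop("duplicate gene_id: ",
         paste(unique(gr$gene_id[duplicated(gr$gene_id)]), collapse = ", "))
  }
  gr$tss <- ifelse(st == "+", GenomicRanges::start(gr),
                   GenomicRanges::end(gr))
  if (!is.null(layout)) {
    validate_intervals(gr, layout, what = "gene")
    gr <- set_layout(gr, layout)
  }
  gr
}

#' Merge intervals within a gap
#'
#' Merges intervals whose pairwise gap is at most `max_gap` bp (the
#' `bedtools merge -d` convention: bookended intervals merge at `max_gap = 0`).
#' Strand is ignored. Output is sorted and non-overlapping; metadata columns
#' are dropped.
#'
#' @param gr A `GRanges`.
#' @param max_gap Maximum gap in bp (>= 0) at which two intervals still merge.
#' @return A sorted, disjoint `GRanges`.
#' @export
merge_intervals <- function(gr, max_gap = 0) {
  if (max_gap < 0) stop("max_gap must be >= 0")
  GenomicRanges::reduce(GenomicRanges::granges(gr),
                        min.gapwidth = max_gap + 1,
                        ignore.strand = TRUE)
}
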