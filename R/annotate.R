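#' Classify genes from a differential-expression table
#'
#' Applies the study's rule: a gene is differentially expressed iff its fold
#' change exceeds 2 in magnitude (`|log2fc| > 1`) with adjusted p < 0.05
#' (direction picks `nb_enriched` vs `immINP_enriched`); it is `invariant`
#' iff `|FC| < 2` regardless of p; anything else (|FC| >= 2 but not
#' significant) is `unclassified`.
#'
#' @param de_table data.frame with `gene_id`, `log2fc`, `padj`.
#' @param fc_threshold Fold-change threshold (linear scale, default 2).
#' @param padj_threshold Adjusted-p threshold (default 0.05).
#' @return The table with a `class` column added.
#' @export
classify_genes <- function(de_table, fc_threshold = 2,
                           padj_threshold = 0.05) {
  need <- c("gene_id", "log2fc", "padj")
  if (!all(need %in% names(de_table))) {
    stop("de_table must have columns: ", paste(need, collapse = ", "))
  }
  if (any(!is.finite(de_table$log2fc))) stop("log2fc must be finite")
  if (any(de_table$padj < 0 | de_table$padj > 1)) {
    stop("padj must lie in [0, 1]")
  }
  l2 <- log2(fc_threshold)
  fc_big <- abs(de_table$log2fc) > l2
  de <- fc_big & de_table$padj < padj_threshold
  cls <- ifelse(de & de_table$log2fc > 0, "nb_enriched",
         ifelse(de, "immINP_enriched",
         ifelse(!fc_big, "invariant", "unclassified")))
  de_table$class <- cls
  de_table
}

#' Two-group t-test with overestimated variance
#'
#' A Welch-style t statistic in which the comparison group's variance term is
#' divided by the focal group's size rather than its own, deliberately
#' overestimating the standard error (the scanpy `t-test_overestim_var`
#' convention); p-values are therefore conservative under the null. The
#' log2 fold change is the log2 ratio of group means.
#'
#' @param expr_a Focal-group expression values (length >= 2, linear scale).
#' @param expr_b Comparison-group values (length >= 2).
#' @return list with `log2fc`, `p`, `t`, `df`.
#' @export
overestim_var_ttest <- function(expr_a, expr_b) {
  stopifnot(length(expr_a) >= 2, length(expr_b) >= 2)
  na <- length(expr_a)
  ma <- mean(expr_a); mb <- mean(expr_b)
  va <- stats::var(expr_a); vb <- stats::var(expr_b)
  eps <- 1e-9
  log2fc <- log2((ma + eps) / (mb + eps))
  if (va == 0 && vb == 0) {
    return(list(log2fc = log2fc, p = 1, t = 0, df = NA_real_))
  }
  se2 <- va / na + vb / na  # both variance terms over the focal group's n
  tstat <- (ma - mb) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / na)^2 / (na - 1))
  p <- 2 * stats::pt(-abs(tstat), df)
  list(log2fc = log2fc, p = p, t = tstat, df = df)
}

#' Annotate peaks against gene models
#'
#' Assigns each peak a genomic category and a gene. The category is decided
#' at the peak summit (falling back to the interval midpoint when no summit
#' is recorded) with precedence promoter > tts > exonic > intronic >
#' intergenic; the promoter window is `(-1000, +100)` bp around the TSS and
#' the TTS window `(-100, +1000)` around the transcript end, both
#' strand-aware. Positions inside a gene body are exonic when an exon
#' annotation is supplied and overlaps, otherwise intronic. Every peak is
#' assigned the gene with the nearest TSS to its summit.
#'
#' @param peaks Peak `GRanges` (optionally with a `summit` column).
#' @param genes Gene `GRanges` from [read_gene_annotation()] (with `gene_id`,
#'   `tss`).
#' @param exons Optional `GRanges` of exons.
#' @param promoter_window `c(upstream, downstream)` bp around the TSS
#'   (upstream negative).
#' @param tts_window `c(upstream, downstream)` bp around the transcript end.
#' @return data.frame with one row per peak: `peak_index`, `chrom`, `start`,
#'   `end`, `summit`, `category`, `assigned_gene`, `tss_distance`.
#' @export
annotate_peaks <- function(peaks, genes, exons = NULL,
                           promoter_window = c(-1000, 100),
                           tts_window = c(-100, 1000)) {
  if (length(genes) == 0) stop("gene annotation is empty")
  if (length(peaks) == 0) {
    return(data.frame(peak_index = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      summit = integer(0), category = character(0),
                      assigned_gene = character(0),
                      tss_distance = numeric(0)))
  }
  summit <- if (!is.null(peaks$summit)) {
    as.integer(peaks$summit)
  } else {
    as.integer(floor((GenomicRanges::start(peaks) +
                        GenomicRanges::end(peaks)) / 2))
  }
  pt <- GenomicRanges::GRanges(GenomicRanges::seqnames(peaks),
                               IRanges::IRanges(summit, width = 1))

  st <- as.character(GenomicRanges::strand(genes))
  tss <- genes$tss
  tes <- ifelse(st == "+", GenomicRanges::end(genes),
                GenomicRanges::start(genes))
  prom <- strand_window(GenomicRanges::seqnames(genes), tss, st,
                        promoter_window)
  ttsr <- strand_window(GenomicRanges::seqnames(genes), tes, st, tts_window)

  in_prom <- IRanges::overlapsAny(pt, prom, ignore.strand = TRUE)
  in_tts <- IRanges::overlapsAny(pt, ttsr, ignore.strand = TRUE)
  in_body <- IRanges::overlapsAny(pt, genes, ignore.strand = TRUE)
  in_exon <- if (!is.null(exons) && length(exons)) {
    IRanges::overlapsAny(pt, exons, ignore.strand = TRUE)
  } else rep(FALSE, length(pt))
  category <- ifelse(in_prom, "promoter",
              ifelse(in_tts, "tts",
              ifelse(in_body & in_exon, "exonic",
              ifelse(in_body, "intronic", "intergenic"))))

  # nearest TSS on the same chromosome
  tss_gr <- GenomicRanges::GRanges(GenomicRanges::seqnames(genes),
                                   IRanges::IRanges(tss, width = 1))
  near <- GenomicRanges::nearest(pt, tss_gr, ignore.strand = TRUE,
                                 select = "arbitrary")
  if (anyNA(near)) {
    # peaks on chromosomes without genes: fall back to global nearest TSS
    for (i in which(is.na(near))) near[i] <- which.min(abs(tss - summit[i]))
  }
  data.frame(peak_index = seq_along(peaks),
             chrom = as.character(GenomicRanges::seqnames(peaks)),
             start = GenomicRanges::start(peaks),
             end = GenomicRanges::end(peaks),
             summit = summit,
             category = category,
             assigned_gene = genes$gene_id[near],
             tss_distance = abs(summit - tss[near]),
             stringsAsFactors = FALSE)
}

# Strand-aware window around a position: offsets are (upstream, downstream)
# in transcription direction; upstream is negative.
strand_window <- function(chrom, pos, strand, window) {
  lo <- ifelse(strand == "+", pos + window[1], pos - window[2])
  hi <- ifelse(strand == "+", pos + window[2], pos - window[1])
  GenomicRanges::GRanges(chrom, IRanges::IRanges(pmax(1, lo), pmax(1, hi)))
}

#' Genomic distribution of annotated peaks
#'
#' @param annotations Output of [annotate_peaks()].
#' @return data.frame with `category`, `count`, `fraction`.
#' @export
genomic_distribution <- function(annotations) {
  lv <- c("promoter", "tts", "exonic", "intronic", "intergenic")
  cnt <- table(factor(annotations$category, levels = lv))
  data.frame(category = lv, count = as.integer(cnt),
             fraction = as.numeric(cnt) / max(1, nrow(annotations)),
             stringsAsFactors = FALSE)
}

#' Fraction of class genes bound by peaks
#'
#' Percentage of genes of a class that have at least one assigned peak.
#'
#' @param annotations Output of [annotate_peaks()].
#' @param gene_classes data.frame with `gene_id`, `class`.
#' @param class Class label to evaluate.
#' @return Percentage in `[0, 100]`.
#' @export
bound_gene_fraction <- function(annotations, gene_classes, class) {
  in_class <- gene_classes$gene_id[gene_classes$class == class]
  if (length(in_class) == 0) stop("no genes of class '", class, "'")
  bound <- unique(annotations$assigned_gene)
  100 * sum(in_class %in% bound) / length(in_class)
}

#' Fraction of one peak set overlapping another
#'
#' Percentage of peaks in `set_a` that overlap at least one peak of `set_b`
#' by >= 1 bp, optionally stratified by a category vector parallel to
#' `set_a`.
#'
#' @param set_a,set_b Peak `GRanges`.
#' @param categories_a Optional character vector (one per peak in `set_a`).
#' @return A single percentage, or a named vector per category.
#' @export
peakset_overlap_fraction <- function(set_a, set_b, categories_a = NULL) {
  if (length(set_a) == 0) stop("set_a is empty")
  hit <- suppressWarnings(
    IRanges::overlapsAny(set_a, set_b, ignore.strand = TRUE))
  if (is.null(categories_a)) {
    return(100 * mean(hit))
  }
  stopifnot(length(categories_a) == length(set_a))
  vapply(split(hit, categories_a), function(h) 100 * mean(h), numeric(1))
}
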