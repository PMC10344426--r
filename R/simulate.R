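#' Simulation configuration
#'
#' Parameters of the synthetic CUT&RUN experiment: a toy genome, a gene set
#' split into neuroblast-enriched / immature-INP-enriched / invariant classes,
#' planted transcription-factor peaks (short-fragment target), planted
#' low-level histone-mark enrichment at a subset of those peaks with a
#' condition-specific fold change, and planted broad Polycomb-like domains.
#'
#' Defaults describe the study regime the simulator emulates: two conditions
#' (control and a mutant in which a fraction of peak-local mark enrichment is
#' lost) with two replicates each, a 2 x 2.5 Mb genome at ~0.02 fragments/bp
#' background, 74% of TF peaks near neuroblast-gene promoters, low-level mark
#' enrichment (3x over background) at half the TF peaks, broad domains at 8x,
#' and negative-binomial fragment counts with dispersion 0.1.
#'
#' @param seed Integer master seed; every stream is derived from it.
#' @param n_chroms,chrom_length Genome shape (identical chromosome lengths).
#' @param background_rate Background fragments per bp per unit depth.
#' @param conditions Character vector of condition labels; the second label
#'   is the "mutant" in which `mutant_fc` applies.
#' @param replicates_per_condition Number of replicates per condition.
#' @param depth_multiplier Named (by sample id) or scalar depth multiplier.
#' @param dispersion Negative-binomial overdispersion phi >= 0 (variance
#'   mu(1 + phi mu)); 0 gives Poisson counts.
#' @param frag_len_tf,frag_len_histone Inclusive fragment-length ranges.
#' @param n_genes Number of genes; `class_fractions` splits them into
#'   nb_enriched / immINP_enriched / invariant.
#' @param n_tf_peaks Number of planted TF peaks.
#' @param tf_peak_width Width of planted TF peaks in bp.
#' @param tf_enrichment Fold enrichment of TF fragments at TF peaks.
#' @param fraction_near_nb Fraction of TF peaks placed inside the promoter
#'   window of an nb_enriched gene.
#' @param low_level_fraction Fraction of TF peaks that also carry low-level
#'   histone-mark enrichment.
#' @param low_level_enrichment Fold enrichment of the mark at those peaks.
#' @param fraction_down Fraction of low-level regions whose mark enrichment
#'   is multiplied by `mutant_fc` in the mutant condition.
#' @param mutant_fc Condition fold change (< 1 = loss) applied in the mutant.
#' @param n_domains Number of planted broad domains.
#' @param domain_width_range Domain width range in bp (>= 5 kb broad regime).
#' @param domain_enrichment Fold enrichment of the mark inside domains.
#' @param promoter_window Promoter window around the TSS, `c(upstream,
#'   downstream)` in bp, used when placing peaks near genes.
#' @param de_jitter SD of the log2 fold-change jitter in the DE table.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 2L,
                       chrom_length = 2.5e6,
                       background_rate = 0.02,
                       conditions = c("control", "mutant"),
                       replicates_per_condition = 2L,
                       depth_multiplier = 1,
                       dispersion = 0.02,
                       frag_len_tf = c(50L, 119L),
                       frag_len_histone = c(150L, 400L),
                       n_genes = 300L,
                       n_tf_peaks = 150L,
                       tf_peak_width = 600L,
                       tf_enrichment = 50,
                       fraction_near_nb = 0.74,
                       low_level_fraction = 0.5,
                       low_level_enrichment = 3,
                       fraction_down = 0.75,
                       mutant_fc = 0.4,
                       n_domains = 12L,
                       domain_width_range = c(5e3, 5e4),
                       domain_enrichment = 8,
                       promoter_window = c(-1000L, 100L),
                       de_jitter = 0.25) {
  cfg <- as.list(environment())
  stopifnot(cfg$background_rate > 0, cfg$dispersion >= 0,
            cfg$mutant_fc > 0, length(cfg$conditions) >= 1,
            cfg$replicates_per_condition >= 1)
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate planted ground truth
#'
#' Builds the genome layout, a stranded gene annotation with planted
#' expression classes, and the truth regions: TF peaks (a configurable
#' fraction placed in promoter windows of nb_enriched genes), low-level
#' histone-mark regions coinciding with a subset of TF peaks (with the mutant
#' fold change planted on a subset of those), and broad domains placed away
#' from TF peaks.
#'
#' @param config A [sim_config()].
#' @return A list with elements `layout` (`Seqinfo`), `genes` (`GRanges` with
#'   `gene_id`, `tss`, `class`), `truth` (`GRanges` with `kind`,
#'   `base_enrichment`, and one `fc_<condition>` column per condition), and
#'   `gene_classes` (data.frame of planted classes).
#' @export
simulate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "truth"))

  chroms <- paste0("chr", seq_len(config$n_chroms))
  layout <- genome_layout(chroms, rep(config$chrom_length, config$n_chroms))
  L <- config$chrom_length

  ## genes: non-overlapping bodies on a jittered grid, random strand
  n_genes <- config$n_genes
  per_chrom <- ceiling(n_genes / config$n_chroms)
  slot <- floor(L / (per_chrom + 1))
  gene_width <- pmin(slot - 200, round(stats::runif(n_genes, 2000, 8000)))
  gene_chrom <- rep(chroms, each = per_chrom)[seq_len(n_genes)]
  slot_idx <- unlist(lapply(seq_len(config$n_chroms), function(i) {
    seq_len(min(per_chrom, n_genes - (i - 1) * per_chrom))
  }))
  gene_start <- (slot_idx - 1) * slot +
    round(stats::runif(n_genes, 100, pmax(101, slot - gene_width - 100)))
  gene_strand <- sample(c("+", "-"), n_genes, replace = TRUE)
  genes <- GenomicRanges::GRanges(
    seqnames = gene_chrom,
    ranges = IRanges::IRanges(start = gene_start + 1,
                              width = pmax(1000, gene_width)),
    strand = gene_strand)
  genes$gene_id <- sprintf("gene%04d", seq_len(n_genes))
  genes$tss <- ifelse(gene_strand == "+", GenomicRanges::start(genes),
                      GenomicRanges::end(genes))
  cls <- sample(rep(c("nb_enriched", "immINP_enriched", "invariant"),
                    times = round(n_genes * c(0.3, 0.2, 0.5)))[seq_len(n_genes)])
  genes$class <- cls
  genes <- set_layout(genes, layout)
  validate_intervals(genes, layout, what = "gene")

  ## TF peaks: fraction_near_nb of them inside promoter windows of NB genes
  n_pk <- config$n_tf_peaks
  w_pk <- config$tf_peak_width
  truth <- GenomicRanges::GRanges()
  if (n_pk > 0) {
    n_near <- round(config$fraction_near_nb * n_pk)
    nb_genes <- genes[genes$class == "nb_enriched"]
    if (n_near > 0 && length(nb_genes) == 0) {
      stop("placement infeasible: no nb_enriched genes to anchor peaks")
    }
    anchor <- nb_genes[sample.int(length(nb_genes), n_near,
                                  replace = n_near > length(nb_genes))]
    up <- config$promoter_window[1]; down <- config$promoter_window[2]
    st <- as.character(GenomicRanges::strand(anchor))
    # centre the peak on a point inside the promoter window
    centre <- ifelse(st == "+",
                     anchor$tss + round(stats::runif(n_near, up, down)),
                     anchor$tss - round(stats::runif(n_near, up, down)))
    near_start <- pmax(1, pmin(L - w_pk, round(centre - w_pk / 2)))
    near <- GenomicRanges::GRanges(
      seqnames = GenomicRanges::seqnames(anchor),
      ranges = IRanges::IRanges(start = near_start, width = w_pk))
    far <- place_nonoverlapping(n_pk - n_near, w_pk, layout,
                                avoid = near, min_gap = 2000)
    peaks <- sort(concat_gr(list(near, far)), ignore.strand = TRUE)
    peaks <- peaks[!duplicated(peaks)]
    # overlapping promoter draws: keep the first of each overlapping pair
    ov <- GenomicRanges::findOverlaps(peaks, drop.self = TRUE,
                                      drop.redundant = TRUE)
    drop <- unique(S4Vectors::subjectHits(ov))
    if (length(drop)) peaks <- peaks[-drop]
    peaks$kind <- "tf_peak"
    peaks$base_enrichment <- config$tf_enrichment
    for (cond in config$conditions) {
      S4Vectors::mcols(peaks)[[paste0("fc_", cond)]] <- 1
    }

    ## low-level mark regions on a subset of TF peaks
    n_low <- round(config$low_level_fraction * length(peaks))
    low <- GenomicRanges::GRanges()
    if (n_low > 0) {
      low <- GenomicRanges::granges(peaks[sample.int(length(peaks), n_low)])
      low$kind <- "low_level_mark"
      low$base_enrichment <- config$low_level_enrichment
      for (cond in config$conditions) {
        S4Vectors::mcols(low)[[paste0("fc_", cond)]] <- 1
      }
      n_down <- round(config$fraction_down * n_low)
      if (n_down > 0 && length(config$conditions) >= 2) {
        mut <- config$conditions[2]
        down_idx <- sample.int(n_low, n_down)
        S4Vectors::mcols(low)[[paste0("fc_", mut)]][down_idx] <-
          config$mutant_fc
      }
    }
    truth <- concat_gr(list(peaks, low))
  }

  ## broad domains away from TF peaks
  if (config$n_domains > 0) {
    widths <- round(stats::runif(config$n_domains,
                                 config$domain_width_range[1],
                                 config$domain_width_range[2]))
    doms <- place_nonoverlapping(config$n_domains, widths, layout,
                                 avoid = GenomicRanges::granges(truth),
                                 min_gap = 5000)
    doms$kind <- "broad_domain"
    doms$base_enrichment <- config$domain_enrichment
    for (cond in config$conditions) {
      S4Vectors::mcols(doms)[[paste0("fc_", cond)]] <- 1
    }
    truth <- concat_gr(list(truth, doms))
  }
  truth <- set_layout(truth, layout)
  if (length(truth)) validate_intervals(truth, layout, what = "truth region")

  gene_classes <- data.frame(gene_id = genes$gene_id, class = genes$class,
                             stringsAsFactors = FALSE)
  list(layout = layout, genes = genes, truth = truth,
       gene_classes = gene_classes)
}

# Rejection-sample n regions of the given widths, uniformly over the genome,
# non-overlapping among themselves and at least min_gap bp from `avoid`.
place_nonoverlapping <- function(n, widths, layout, avoid = NULL,
                                 min_gap = 0, max_tries = 1000) {
  if (n <= 0) {
    return(GenomicRanges::GRanges(seqinfo = layout))
  }
  widths <- rep_len(widths, n)
  chroms <- GenomeInfoDb::seqnames(layout)
  lens <- GenomeInfoDb::seqlengths(layout)
  blocked <- if (is.null(avoid) || length(avoid) == 0) {
    GenomicRanges::GRanges()
  } else {
    # strip seqinfo before padding: padded regions may poke past chromosome
    # ends, which is fine for a block list
    av <- GenomicRanges::GRanges(
      GenomicRanges::seqnames(avoid),
      IRanges::ranges(GenomicRanges::granges(avoid)))
    GenomicRanges::resize(av, GenomicRanges::width(av) + 2 * min_gap,
                          fix = "center")
  }
  placed <- GenomicRanges::GRanges()
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      ch <- sample(chroms, 1, prob = as.numeric(lens))
      maxs <- lens[[ch]] - widths[i]
      if (maxs < 1) next
      s <- 1 + floor(stats::runif(1) * maxs)
      cand <- GenomicRanges::GRanges(ch, IRanges::IRanges(s, width = widths[i]))
      pad <- GenomicRanges::resize(cand, widths[i] + 2 * min_gap,
                                   fix = "center")
      hit <- suppressWarnings(
        IRanges::overlapsAny(pad, blocked, ignore.strand = TRUE) ||
          IRanges::overlapsAny(pad, placed, ignore.strand = TRUE))
      if (!hit) {
        placed <- concat_gr(list(placed, cand))
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("placement infeasible: could not place region ", i)
  }
  sort(set_layout(placed, layout))
}

#' Simulate one sample's fragments
#'
#' Fragment counts per genomic segment are negative binomial with mean
#' `background_rate x depth x prod(enrichments)` per bp and variance
#' `mu(1 + phi mu)`; dispersion 0 gives Poisson counts. Fragment starts are
#' uniform within their segment; lengths are uniform in the target's range
#' (TF: sub-nucleosomal, histone: nucleosomal); fragments that would overrun
#' the chromosome are redrawn. TF samples see `tf_peak` enrichment; histone
#' samples see `broad_domain` and `low_level_mark` enrichment (times the
#' region's condition fold change).
#'
#' @param truth Output of [simulate_truth()].
#' @param config The [sim_config()].
#' @param condition Condition label (must be in `config$conditions`).
#' @param replicate Replicate number.
#' @param target `"tf"` or `"histone"`.
#' @param depth Depth multiplier for this sample (default from config).
#' @return A [fragment_set()].
#' @export
simulate_fragments <- function(truth, config, condition, replicate = 1L,
                               target = c("histone", "tf"), depth = NULL) {
  target <- match.arg(target)
  stopifnot(condition %in% config$conditions)
  if (is.null(depth)) {
    dm <- config$depth_multiplier
    sid <- paste(condition, replicate, target, sep = "_")
    depth <- if (length(dm) > 1 && !is.null(names(dm)) && sid %in% names(dm)) {
      dm[[sid]]
    } else dm[[1]]
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  sid <- paste(condition, replicate, target, sep = "_")
  set.seed(derive_seed(config$seed, paste0("frag:", sid)))

  kinds <- if (target == "tf") "tf_peak" else c("broad_domain", "low_level_mark")
  regions <- truth$truth[truth$truth$kind %in% kinds]
  fc_col <- paste0("fc_", condition)
  mult <- if (length(regions)) {
    regions$base_enrichment * S4Vectors::mcols(regions)[[fc_col]]
  } else numeric(0)

  len_range <- if (target == "tf") config$frag_len_tf else config$frag_len_histone
  lens <- GenomeInfoDb::seqlengths(truth$layout)
  all_frags <- list()
  for (ch in GenomeInfoDb::seqnames(truth$layout)) {
    L <- lens[[ch]]
    reg_ch <- regions[as.character(GenomicRanges::seqnames(regions)) == ch]
    mult_ch <- mult[as.character(GenomicRanges::seqnames(regions)) == ch]
    # piecewise-constant rate segments: background split by region boundaries
    bounds <- sort(unique(c(1, L + 1,
                            GenomicRanges::start(reg_ch),
                            GenomicRanges::end(reg_ch) + 1)))
    seg_start <- bounds[-length(bounds)]
    seg_end <- bounds[-1] - 1
    seg_w <- seg_end - seg_start + 1
    seg_rate <- rep(config$background_rate * depth, length(seg_start))
    if (length(reg_ch)) {
      mids <- (seg_start + seg_end) / 2
      hit <- GenomicRanges::findOverlaps(
        GenomicRanges::GRanges(ch, IRanges::IRanges(floor(mids), width = 1)),
        reg_ch)
      # regions of the same kind never overlap; multipliers multiply across kinds
      for (j in seq_along(S4Vectors::queryHits(hit))) {
        q <- S4Vectors::queryHits(hit)[j]
        s <- S4Vectors::subjectHits(hit)[j]
        seg_rate[q] <- seg_rate[q] * mult_ch[s]
      }
    }
    # draw counts per fixed-width tile inside each segment so that
    # overdispersion acts at a local scale (it then surfaces as
    # replicate-to-replicate window variance, not as chromosome-length
    # rate drifts no real sample shows)
    tile <- 500L
    n_t <- ceiling(seg_w / tile)
    seg_of <- rep(seq_along(seg_start), n_t)
    tile_start <- seg_start[seg_of] + (sequence(n_t) - 1) * tile
    tile_w <- pmin(tile_start + tile - 1, seg_end[seg_of]) - tile_start + 1
    mu <- seg_rate[seg_of] * tile_w
    counts <- if (config$dispersion > 0) {
      stats::rnbinom(length(mu), size = 1 / config$dispersion, mu = mu)
    } else {
      stats::rpois(length(mu), mu)
    }
    tot <- sum(counts)
    if (tot == 0) next
    starts <- rep(tile_start, counts) +
      floor(stats::runif(tot) * rep(tile_w, counts))
    flen <- len_range[1] +
      floor(stats::runif(tot) * (len_range[2] - len_range[1] + 1))
    over <- starts + flen - 1 > L
    tries <- 0
    while (any(over) && tries < 100) {
      flen[over] <- len_range[1] +
        floor(stats::runif(sum(over)) * (len_range[2] - len_range[1] + 1))
      starts[over] <- pmin(starts[over], L - flen[over] + 1)
      over <- starts + flen - 1 > L
      tries <- tries + 1
    }
    all_frags[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = starts, width = flen))
  }
  gr <- if (length(all_frags)) {
    sort(concat_gr(all_frags))
  } else {
    GenomicRanges::GRanges()
  }
  fragment_set(gr, sample_id = sid, condition = condition,
               replicate = replicate, target = target, layout = truth$layout)
}

#' Simulate a differential-expression table
#'
#' Emits one row per gene with a jittered log2 fold change and adjusted
#' p-value consistent with its planted class: nb_enriched genes get
#' |log2FC| > 1 (fold change > 2) with padj < 0.05, immINP_enriched the
#' mirror image, invariant genes |log2FC| < 1. At the default jitter the
#' downstream classifier recovers the planted class for >= 99% of genes.
#'
#' @param truth Output of [simulate_truth()].
#' @param config The [sim_config()].
#' @return A data.frame with columns `gene_id`, `log2fc`, `padj`.
#' @export
simulate_de_table <- function(truth, config) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(derive_seed(config$seed, "de_table"))
  cls <- truth$gene_classes
  n <- nrow(cls)
  log2fc <- numeric(n)
  padj <- numeric(n)
  j <- config$de_jitter
  up <- cls$class == "nb_enriched"
  dn <- cls$class == "immINP_enriched"
  inv <- cls$class == "invariant"
  log2fc[up] <- 1.6 + abs(stats::rnorm(sum(up), 0, j))
  log2fc[dn] <- -(1.6 + abs(stats::rnorm(sum(dn), 0, j)))
  log2fc[inv] <- stats::runif(sum(inv), -0.9, 0.9)
  padj[up | dn] <- stats::runif(sum(up | dn), 1e-6, 0.04)
  padj[inv] <- stats::runif(sum(inv), 0, 1)
  data.frame(gene_id = cls$gene_id, log2fc = log2fc, padj = padj,
             stringsAsFactors = FALSE)
}

#' Simulate a full experiment
#'
#' Convenience wrapper: truth, histone-mark fragment sets for every
#' condition x replicate, one sub-nucleosomal TF sample per TF replicate in
#' the first (control) condition, and the DE table.
#'
#' @param config A [sim_config()].
#' @param tf_replicates Number of TF replicates (control condition).
#' @return A list with `truth`, `histone` (list of FragmentSet),
#'   `tf` (list of FragmentSet), `de_table`.
#' @export
simulate_experiment <- function(config, tf_replicates = 2L) {
  truth <- simulate_truth(config)
  histone <- list()
  for (cond in config$conditions) {
    for (r in seq_len(config$replicates_per_condition)) {
      fs <- simulate_fragments(truth, config, cond, r, target = "histone")
      histone[[fs$sample_id]] <- fs
    }
  }
  tf <- list()
  for (r in seq_len(tf_replicates)) {
    fs <- simulate_fragments(truth, config, config$conditions[1], r,
                             target = "tf")
    tf[[fs$sample_id]] <- fs
  }
  list(truth = truth, histone = histone, tf = tf,
       de_table = simulate_de_table(truth, config))
}

#' Write truth files
#'
#' Serializes the planted truth as plain-text inputs: layout as a
#' chromosome-sizes file, truth regions as BED6 (name = kind, score =
#' base_enrichment) plus a TSV with per-condition fold changes, genes as
#' BED6, classes as TSV.
#'
#' @param truth Output of [simulate_truth()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the directory.
#' @export
write_truth <- function(truth, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_chrom_sizes(truth$layout, file.path(dir, "layout.chrom.sizes"))
  tr <- truth$truth
  if (length(tr)) {
    bed <- GenomicRanges::granges(tr)
    bed$name <- tr$kind
    bed$score <- tr$base_enrichment
    write_bed(bed, file.path(dir, "truth_regions.bed"))
    utils::write.table(
      cbind(as.data.frame(GenomicRanges::granges(tr))[, 1:3],
            as.data.frame(S4Vectors::mcols(tr))),
      file.path(dir, "truth_regions.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    file.create(file.path(dir, "truth_regions.bed"))
  }
  gb <- GenomicRanges::granges(truth$genes)
  gb$name <- truth$genes$gene_id
  write_bed(gb, file.path(dir, "genes.bed"))
  utils::write.table(truth$gene_classes, file.path(dir, "gene_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(dir)
}
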