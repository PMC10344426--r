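#' Sliding-window fragment counts
#'
#' Tiles each chromosome with windows of `window` bp every `step` bp and
#' counts each sample's fragments per window (>= 1 bp overlap). Chromosomes
#' shorter than the window are skipped with a warning.
#'
#' @param frag_sets List of `FragmentSet`s (both conditions, all replicates).
#' @param layout `Seqinfo` layout.
#' @param window Window size in bp (default 500).
#' @param step Step size in bp (default 100).
#' @return A list of class `window_scan`: `windows` (`GRanges`), `counts`
#'   (windows x samples matrix), `samples` (data.frame with `sample_id`,
#'   `condition`, `replicate`).
#' @export
window_scan <- function(frag_sets, layout, window = 500, step = 100) {
  stopifnot(length(frag_sets) >= 1)
  lens <- GenomeInfoDb::seqlengths(layout)
  chroms <- GenomeInfoDb::seqnames(layout)
  wins <- list()
  for (ch in chroms) {
    L <- lens[[ch]]
    if (L < window) {
      warning(sprintf("chromosome %s (%d bp) shorter than window; skipped",
                      ch, L))
      next
    }
    starts <- seq(1L, L - window + 1L, by = step)
    wins[[ch]] <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(start = starts, width = window))
  }
  if (!length(wins)) stop("no chromosome long enough for the window size")
  windows <- set_layout(concat_gr(wins), layout)
  counts <- vapply(frag_sets, function(fs) {
    GenomicRanges::countOverlaps(windows, as_fragments(fs),
                                 ignore.strand = TRUE)
  }, integer(length(windows)))
  if (is.null(dim(counts))) counts <- matrix(counts, ncol = length(frag_sets))
  samples <- data.frame(
    sample_id = vapply(frag_sets, function(fs) {
      if (inherits(fs, "FragmentSet")) fs$sample_id else NA_character_
    }, character(1)),
    condition = vapply(frag_sets, function(fs) {
      if (inherits(fs, "FragmentSet")) fs$condition else NA_character_
    }, character(1)),
    replicate = vapply(frag_sets, function(fs) {
      if (inherits(fs, "FragmentSet")) fs$replicate else NA_integer_
    }, integer(1)),
    stringsAsFactors = FALSE)
  if (anyNA(samples$sample_id)) {
    samples$sample_id <- names(frag_sets) %||%
      paste0("sample", seq_along(frag_sets))
  }
  colnames(counts) <- samples$sample_id
  structure(list(windows = windows, counts = counts, samples = samples),
            class = "window_scan")
}

#' Build a window scan from a precomputed count matrix
#'
#' @param windows `GRanges` of windows.
#' @param counts Matrix windows x samples.
#' @param condition Character vector of per-sample condition labels.
#' @return A `window_scan` object.
#' @export
window_scan_from_counts <- function(windows, counts, condition) {
  stopifnot(nrow(counts) == length(windows),
            ncol(counts) == length(condition))
  samples <- data.frame(
    sample_id = colnames(counts) %||% paste0("sample", seq_len(ncol(counts))),
    condition = condition,
    replicate = stats::ave(seq_along(condition), condition,
                           FUN = seq_along),
    stringsAsFactors = FALSE)
  colnames(counts) <- samples$sample_id
  structure(list(windows = windows, counts = counts, samples = samples),
            class = "window_scan")
}

#' Test windows for differential enrichment
#'
#' Normalizes each sample's window counts by its final scale factor (the
#' scale vector is first rescaled to geometric mean 1, so only the factors'
#' ratios matter) and compares conditions with a negative-binomial exact
#' test: replicate counts are pooled per condition and, conditional on the
#' pooled total, the control share is tested against its null expectation
#' under NB sampling with a common dispersion estimated across windows by
#' method of moments (dispersion 0 reduces to a conditional binomial test;
#' with a single replicate per condition a G-test on pooled counts is used).
#' Windows whose pooled normalized count falls below `min_count` are not
#' tested. P-values are BH-adjusted over tested windows; log2 fold changes
#' (treatment vs control) come from normalized condition means with a
#' pseudocount of 0.5 (used for fold change only, never for testing).
#'
#' @param scan A `window_scan`.
#' @param scale_factors Named numeric vector of per-sample final scale
#'   factors (from [final_scale_factor()]); order matches scan samples if
#'   unnamed.
#' @param control,treatment Condition labels; fold changes are
#'   treatment over control.
#' @param alpha Significance cutoff on q for the `direction` call.
#' @param min_count Minimum pooled normalized count for testing.
#' @param dispersion Common NB dispersion phi, or `NULL` to estimate.
#' @return data.frame (one row per window): coordinates, per-sample
#'   normalized counts, `mean_control`, `mean_treatment`, `log2fc`,
#'   `pvalue`, `qvalue`, `direction` (`up`/`down`/`ns`), `tested`.
#' @export
test_windows <- function(scan, scale_factors, control, treatment,
                         alpha = 0.05, min_count = 10, dispersion = NULL) {
  stopifnot(inherits(scan, "window_scan"))
  cond <- scan$samples$condition
  if (!all(c(control, treatment) %in% cond)) {
    stop("both condition labels must be present among the samples")
  }
  if (length(unique(cond)) < 2) stop("need two conditions to test")
  sf <- scale_factors
  if (!is.null(names(sf))) sf <- sf[scan$samples$sample_id]
  if (length(sf) != ncol(scan$counts) || any(!is.finite(sf)) ||
      any(sf <= 0)) {
    stop("need one positive scale factor per sample")
  }
  rel <- sf / exp(mean(log(sf)))  # geometric mean 1: only ratios matter
  x <- sweep(scan$counts, 2, rel, `*`)

  a_idx <- which(cond == control)
  b_idx <- which(cond == treatment)
  n1 <- length(a_idx); n2 <- length(b_idx)
  m1 <- rowMeans(x[, a_idx, drop = FALSE])
  m2 <- rowMeans(x[, b_idx, drop = FALSE])
  pooled <- n1 * m1 + n2 * m2
  tested <- pooled >= min_count

  if (is.null(dispersion)) {
    dispersion <- estimate_dispersion_mom(x, cond)
  }
  phi <- dispersion

  y1 <- round(rowSums(x[, a_idx, drop = FALSE]))
  y2 <- round(rowSums(x[, b_idx, drop = FALSE]))
  pv <- rep(NA_real_, nrow(x))
  if (n1 >= 2 || n2 >= 2) {
    pv[tested] <- nb_exact_pvalues(y1[tested], y2[tested], n1, n2, phi)
  } else {
    pv[tested] <- gtest_pvalues(y1[tested], y2[tested],
                                n1 / (n1 + n2))
  }
  qv <- rep(NA_real_, nrow(x))
  qv[tested] <- stats::p.adjust(pv[tested], method = "BH")

  log2fc <- log2((m2 + 0.5) / (m1 + 0.5))
  direction <- rep("ns", nrow(x))
  sig <- tested & !is.na(qv) & qv < alpha
  direction[sig & log2fc > 0] <- "up"
  direction[sig & log2fc < 0] <- "down"

  out <- data.frame(
    chrom = as.character(GenomicRanges::seqnames(scan$windows)),
    start = GenomicRanges::start(scan$windows),
    end = GenomicRanges::end(scan$windows),
    stringsAsFactors = FALSE)
  norm_df <- as.data.frame(x)
  names(norm_df) <- paste0("norm_", scan$samples$sample_id)
  out <- cbind(out, norm_df)
  out$mean_control <- m1
  out$mean_treatment <- m2
  out$log2fc <- log2fc
  out$pvalue <- pv
  out$qvalue <- qv
  out$direction <- direction
  out$tested <- tested
  attr(out, "dispersion") <- phi
  attr(out, "conditions") <- c(control = control, treatment = treatment)
  out
}

# Pooled method-of-moments estimate of the common NB dispersion phi
# (variance mu(1 + phi mu)) from normalized counts, using within-condition
# replicate means and variances across all windows. Bias in the squared-mean
# denominator is corrected by subtracting var/n.
estimate_dispersion_mom <- function(x, cond) {
  num <- 0; den <- 0
  for (cc in unique(cond)) {
    idx <- which(cond == cc)
    if (length(idx) < 2) next
    m <- rowMeans(x[, idx, drop = FALSE])
    v <- apply(x[, idx, drop = FALSE], 1, stats::var)
    use <- m > 0
    num <- num + sum(v[use] - m[use])
    den <- den + sum(pmax(m[use]^2 - v[use] / length(idx), 0))
  }
  if (den <= 0) return(0)
  max(0, num / den)
}

# Exact conditional NB test. Under H0 the two pooled counts are
# NB(n_c * lambda, size = n_c/phi); conditional on the total s, the control
# count's distribution is the normalized product of the two NB pmfs at the
# H0 means (q1 = n1/(n1+n2) share). Two-sided p sums all outcomes no more
# probable than the observed one. Memoized over unique totals.
nb_exact_pvalues <- function(y1, y2, n1, n2, phi) {
  s_all <- y1 + y2
  q1 <- n1 / (n1 + n2)
  pmf_for_s <- function(s) {
    if (s == 0) return(1)
    k <- 0:s
    if (phi <= 0) {
      lp <- stats::dbinom(k, s, q1, log = TRUE)
    } else {
      lam <- s / (n1 + n2)
      lp <- stats::dnbinom(k, size = n1 / phi, mu = n1 * lam, log = TRUE) +
        stats::dnbinom(s - k, size = n2 / phi, mu = n2 * lam, log = TRUE)
      lp <- lp - max(lp)
    }
    p <- exp(lp)
    p / sum(p)
  }
  cache <- new.env(parent = emptyenv())
  pv <- numeric(length(s_all))
  for (i in seq_along(s_all)) {
    s <- s_all[i]
    key <- as.character(s)
    pmf <- if (!is.null(cache[[key]])) cache[[key]] else {
      cache[[key]] <- pmf_for_s(s)
      cache[[key]]
    }
    p_obs <- pmf[y1[i] + 1]
    pv[i] <- min(1, sum(pmf[pmf <= p_obs * (1 + 1e-12)]))
  }
  pv
}

# Two-cell G-test of the pooled split against the null share q1.
gtest_pvalues <- function(y1, y2, q1) {
  s <- y1 + y2
  e1 <- s * q1
  e2 <- s * (1 - q1)
  term <- function(o, e) ifelse(o > 0, o * log(o / e), 0)
  g <- 2 * (term(y1, e1) + term(y2, e2))
  stats::pchisq(g, df = 1, lower.tail = FALSE)
}

#' Flag windows overlapping reference peaks
#'
#' Adds a logical `bound` column: `TRUE` for windows overlapping any
#' reference peak by >= 1 bp.
#'
#' @param diff_table Output of [test_windows()].
#' @param reference_peaks `GRanges` of reference (e.g. TF) peaks.
#' @return The table with a `bound` column.
#' @export
mark_bound <- function(diff_table, reference_peaks) {
  gr <- GenomicRanges::GRanges(
    diff_table$chrom,
    IRanges::IRanges(diff_table$start, diff_table$end))
  diff_table$bound <- IRanges::overlapsAny(gr, reference_peaks,
                                           ignore.strand = TRUE)
  diff_table
}

#' Summarize differential windows as kb fractions
#'
#' Merges significant windows into maximal runs (overlapping or bookended
#' windows unify) before accounting, then reports total significant kb, kb
#' with a greater-than-`fc_threshold`-fold increase, kb with a greater-than-
#' `fc_threshold`-fold decrease, their percentages of the significant total,
#' and (when a `bound` column is present) the same restricted to bound and
#' to unbound windows.
#'
#' @param diff_table Output of [test_windows()] (optionally [mark_bound()]).
#' @param fc_threshold Fold-change threshold (linear, default 2).
#' @param alpha Significance cutoff on q.
#' @return data.frame with one row per stratum (`all`, `bound`, `unbound`):
#'   `total_sig_kb`, `up_kb`, `down_kb`, `up_pct`, `down_pct`.
#' @export
summarize_fc <- function(diff_table, fc_threshold = 2, alpha = 0.05) {
  l2 <- log2(fc_threshold)
  strata <- list(all = rep(TRUE, nrow(diff_table)))
  if (!is.null(diff_table$bound)) {
    strata$bound <- diff_table$bound
    strata$unbound <- !diff_table$bound
  }
  one <- function(keep) {
    tab <- diff_table[keep, , drop = FALSE]
    sig <- !is.na(tab$qvalue) & tab$qvalue < alpha
    kb <- function(rows) {
      if (!any(rows)) return(0)
      gr <- GenomicRanges::GRanges(
        tab$chrom[rows], IRanges::IRanges(tab$start[rows], tab$end[rows]))
      sum(GenomicRanges::width(GenomicRanges::reduce(gr))) / 1000
    }
    total <- kb(sig)
    up <- kb(sig & tab$log2fc > l2)
    down <- kb(sig & tab$log2fc < -l2)
    c(total_sig_kb = total, up_kb = up, down_kb = down,
      up_pct = if (total > 0) 100 * up / total else 0,
      down_pct = if (total > 0) 100 * down / total else 0)
  }
  res <- t(vapply(strata, one, numeric(5)))
  data.frame(stratum = rownames(res), res, row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Export a volcano table
#'
#' Plotting-ready table of log2 fold change against `-log10(q)` (the q = 0.05
#' reference line sits at 1.301), with the bound flag when present.
#'
#' @param diff_table Output of [test_windows()].
#' @param path Optional TSV output path.
#' @return data.frame with `log2fc`, `neglog10_q`, `bound`.
#' @export
volcano_table <- function(diff_table, path = NULL) {
  tab <- diff_table[diff_table$tested, , drop = FALSE]
  out <- data.frame(
    log2fc = tab$log2fc,
    neglog10_q = -log10(tab$qvalue),
    bound = if (!is.null(tab$bound)) tab$bound else NA,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  out
}
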