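# Independent brute-force oracles and small fixture builders used across the
# suite. Each oracle is written from the operation's definition, not from the
# package implementation.

toy_layout <- function(n = 2, len = 1e5) {
  genome_layout(paste0("chr", seq_len(n)), rep(len, n))
}

random_intervals <- function(n, layout, max_width = 500, seed = 1) {
  set.seed(seed)
  lens <- GenomeInfoDb::seqlengths(layout)
  ch <- sample(names(lens), n, replace = TRUE)
  w <- sample.int(max_width, n, replace = TRUE)
  s <- vapply(seq_len(n), function(i) {
    sample.int(lens[[ch[i]]] - w[i], 1)
  }, integer(1))
  GenomicRanges::GRanges(ch, IRanges::IRanges(s, width = w))
}

# O(n^2) union-with-gap merge: repeatedly fuse any two intervals whose gap
# is <= max_gap until no pair fuses.
oracle_merge <- function(gr, max_gap) {
  df <- data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
                   start = GenomicRanges::start(gr),
                   end = GenomicRanges::end(gr))
  changed <- TRUE
  while (changed) {
    changed <- FALSE
    i <- 1
    while (i <= nrow(df)) {
      j <- i + 1
      while (j <= nrow(df)) {
        same <- df$chrom[i] == df$chrom[j]
        gap <- max(df$start[i], df$start[j]) -
          min(df$end[i], df$end[j]) - 1
        if (same && gap <= max_gap) {
          df$start[i] <- min(df$start[i], df$start[j])
          df$end[i] <- max(df$end[i], df$end[j])
          df <- df[-j, , drop = FALSE]
          changed <- TRUE
        } else {
          j <- j + 1
        }
      }
      i <- i + 1
    }
  }
  df <- df[order(df$chrom, df$start), ]
  GenomicRanges::GRanges(df$chrom, IRanges::IRanges(df$start, df$end))
}

# Brute-force pairwise >= 1 bp overlap counts of fragments in regions.
oracle_region_counts <- function(frags, regions) {
  fc <- as.character(GenomicRanges::seqnames(frags))
  fs <- GenomicRanges::start(frags)
  fe <- GenomicRanges::end(frags)
  vapply(seq_along(regions), function(i) {
    rc <- as.character(GenomicRanges::seqnames(regions))[i]
    rs <- GenomicRanges::start(regions)[i]
    re <- GenomicRanges::end(regions)[i]
    sum(fc == rc & fs <= re & fe >= rs)
  }, numeric(1))
}

# Brute-force TMM written directly from the trimmed-mean-of-M-values
# definition (reference by upper quartile, per-tail trimming by explicit
# sorting, delta-method weights, geometric-mean-1 rescaling).
oracle_tmm <- function(counts) {
  counts <- as.matrix(counts)
  n_s <- ncol(counts)
  lib <- colSums(counts)
  uq <- numeric(n_s)
  for (j in seq_len(n_s)) {
    uq[j] <- unname(stats::quantile(counts[, j], 0.75)) / lib[j]
  }
  ref <- order(abs(uq - mean(uq)))[1]
  f <- numeric(n_s)
  for (j in seq_len(n_s)) {
    obs <- counts[, j]; rf <- counts[, ref]
    ok <- obs > 0 & rf > 0
    obs <- obs[ok]; rf <- rf[ok]
    M <- log2((obs / lib[j]) / (rf / lib[ref]))
    A <- (log2(obs / lib[j]) + log2(rf / lib[ref])) / 2
    w <- (lib[j] - obs) / (lib[j] * obs) + (lib[ref] - rf) / (lib[ref] * rf)
    if (length(M) < 2 || max(abs(M)) < 1e-6) { f[j] <- 1; next }
    n <- length(M)
    keepM <- logical(n); keepA <- logical(n)
    oM <- order(M); oA <- order(A)
    loL <- floor(n * 0.3) + 1; hiL <- n + 1 - loL
    loS <- floor(n * 0.05) + 1; hiS <- n + 1 - loS
    rM <- rank(M); rA <- rank(A)
    keep <- rM >= loL & rM <= hiL & rA >= loS & rA <= hiS
    f[j] <- 2^(sum(M[keep] / w[keep]) / sum(1 / w[keep]))
  }
  f / exp(mean(log(f)))
}

# Pool the fragments of one condition's samples into a single GRanges.
concat_ctrl <- function(samples, condition) {
  keep <- vapply(samples, function(f) f$condition == condition, logical(1))
  suppressWarnings(do.call(c, unname(lapply(samples[keep],
                                            function(f) f$fragments))))
}

# Simulate one histone experiment (all four samples) from a config.
sim_histone_samples <- function(cfg) {
  tr <- simulate_truth(cfg)
  out <- list()
  for (cond in cfg$conditions) {
    for (r in seq_len(cfg$replicates_per_condition)) {
      fs <- simulate_fragments(tr, cfg, cond, r, target = "histone")
      out[[fs$sample_id]] <- fs
    }
  }
  list(truth = tr, samples = out)
}
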