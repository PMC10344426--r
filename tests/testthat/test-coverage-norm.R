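test_that("binned coverage counts every >=1 bp bin overlap", {
  layout <- genome_layout("chr1", 100)
  frag <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 25))  # [0,25)
  tr <- compute_coverage(frag, layout, bin_size = 10)
  expect_equal(tr$values$chr1[1:4], c(1, 1, 1, 0))

  dup <- c(frag, frag)
  expect_equal(compute_coverage(dup, layout, 10)$values$chr1[1], 2)
  expect_equal(compute_coverage(dup, layout, 10, dedup = TRUE)$values$chr1[1], 1)

  long <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 130))
  tr2 <- compute_coverage(c(frag, long), layout, 10,
                          max_fragment_length = 120)
  expect_equal(sum(tr2$values$chr1), 3)  # 130 bp fragment excluded
})

test_that("binned coverage equals the brute-force overlap oracle", {
  layout <- toy_layout(2, 5000)
  frags <- random_intervals(1000, layout, max_width = 300, seed = 2)
  tr <- compute_coverage(frags, layout, bin_size = 100)
  for (ch in c("chr1", "chr2")) {
    bins <- GenomicRanges::GRanges(
      ch, IRanges::IRanges(seq(1, 5000, by = 100), width = 100))
    expect_equal(tr$values[[ch]], oracle_region_counts(frags, bins))
  }
})

test_that("RPKM and scale transforms apply the exact formulas", {
  layout <- genome_layout("chr1", 100)
  tr <- binned_track(list(chr1 = c(1, 0, 0, 0, 0, 0, 0, 0, 0, 0)),
                     layout, 10, "raw")
  r <- to_rpkm(tr, 1e6)
  expect_equal(r$values$chr1[1], 100)         # 1e9 / (10 * 1e6)
  expect_equal(to_rpkm(tr, 2e6)$values$chr1[1], 50)  # doubling halves
  expect_error(to_rpkm(tr, 0), "total_fragments")
  expect_error(to_rpkm(r, 10), "raw")

  s <- scale_track(tr, 0.5)
  expect_equal(s$values$chr1[1], 0.5)
  expect_identical(s$state, "scaled")
})

test_that("replicate merge is a per-bin mean on identical grids", {
  layout <- genome_layout("chr1", 30)
  t1 <- binned_track(list(chr1 = c(2, 0, 4)), layout, 10, "raw")
  t2 <- binned_track(list(chr1 = c(4, 0, 8)), layout, 10, "raw")
  m <- merge_replicates(list(t1, t2))
  expect_equal(m$values$chr1, c(3, 0, 6))
  expect_equal(merge_replicates(list(t1, t1))$values$chr1, t1$values$chr1)
  t3 <- binned_track(list(chr1 = c(1, 1)), genome_layout("chr1", 20), 10,
                     "raw")
  expect_error(merge_replicates(list(t1, t3)), "share")
})

test_that("z-score normalization gives mean 0 sd 1 and handles sd = 0", {
  layout <- genome_layout("chr1", 30)
  tr <- binned_track(list(chr1 = c(1, 2, 3)), layout, 10, "raw")
  z <- zscore_normalize(tr)
  expect_equal(z$values$chr1, c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
  expect_equal(round(z$values$chr1[3], 4), 1.2247)  # population sd sqrt(2/3)
  v <- unlist(z$values)
  expect_lt(abs(mean(v)), 1e-9)
  expect_lt(abs(sqrt(mean((v - mean(v))^2)) - 1), 1e-9)
  # idempotence
  expect_equal(zscore_normalize(z)$values$chr1, z$values$chr1)
  flat <- binned_track(list(chr1 = c(5, 5, 5)), layout, 10, "raw")
  expect_warning(z0 <- zscore_normalize(flat), "zero variance")
  expect_equal(z0$values$chr1, c(0, 0, 0))
})

test_that("region counting matches the pairwise oracle", {
  layout <- toy_layout(2, 2e4)
  frags <- random_intervals(500, layout, max_width = 400, seed = 31)
  regions <- random_intervals(20, layout, max_width = 2000, seed = 77)
  expect_equal(as.numeric(count_in_regions(frags, regions)),
               oracle_region_counts(frags, regions))
  # a fragment spanning two regions is counted in both
  f <- GenomicRanges::GRanges("chr1", IRanges::IRanges(90, 210))
  r2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 200), c(100, 300)))
  expect_equal(as.numeric(count_in_regions(f, r2)), c(1, 1))
})

test_that("TMM factors absorb pure depth differences", {
  set.seed(1)
  a <- rnbinom(2000, mu = 100, size = 10)
  m <- cbind(a = a, b = 2L * a)
  f <- tmm_factors(m)
  expect_equal(unname(f), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(tmm_factors(cbind(a, a))), c(1, 1))
})

test_that("TMM matches the independent brute-force oracle", {
  for (seed in 1:4) {
    set.seed(seed)
    m <- matrix(rnbinom(2000 * 4, mu = exp(runif(2000, 2, 6)), size = 5),
                ncol = 4)
    m <- m[rowSums(m) > 0, ]
    expect_equal(unname(tmm_factors(m)), oracle_tmm(m), tolerance = 1e-6)
  }
  # composition bias: inflate 10% of regions in one sample only
  set.seed(9)
  base <- rnbinom(2000, mu = 200, size = 20)
  b <- base
  idx <- sample.int(2000, 200)
  b[idx] <- b[idx] * 4L
  # the inflated library's factor drops below its partner's: its unchanged
  # regions look depleted relative to its inflated library size
  f <- tmm_factors(cbind(base, b))
  expect_lt(unname(f[2] / f[1]), 1)
  expect_equal(unname(tmm_factors(cbind(base, b))),
               oracle_tmm(cbind(base, b)), tolerance = 1e-6)
})

test_that("TMM agrees with the edgeR reference implementation", {
  skip_if_not_installed("edgeR")
  set.seed(3)
  m <- matrix(rnbinom(5000 * 6, mu = exp(runif(5000, 2, 7)), size = 8),
              ncol = 6)
  m <- m[rowSums(m) > 0, ]
  ours <- unname(tmm_factors(m))
  ref <- unname(edgeR::calcNormFactors(m, method = "TMM"))
  expect_equal(ours, ref, tolerance = 1e-6)
})

test_that("the final scale factor is 1e6/(tmm x reads-in-peaks)", {
  expect_identical(final_scale_factor(1.25, 8e5), 1)
  expect_identical(final_scale_factor(1, 1e6), 1)
  expect_equal(final_scale_factor(0.8, 2.5e6), 0.5)
  expect_error(final_scale_factor(0, 10), "tmm_factor")
  expect_error(final_scale_factor(1, 0), "reads_in_peaks")
})

test_that("scaled tracks of depth-only-different samples agree in expectation", {
  cfg <- sim_config(seed = 19, dispersion = 0, n_tf_peaks = 40L,
                    n_domains = 4L, low_level_fraction = 0,
                    domain_width_range = c(5e3, 1.5e4),
                    n_chroms = 1L, chrom_length = 1e6,
                    background_rate = 0.05,
                    depth_multiplier = c(control_1_histone = 1,
                                         control_2_histone = 2))
  tr <- simulate_truth(cfg)
  f1 <- simulate_fragments(tr, cfg, "control", 1, "histone")
  f2 <- simulate_fragments(tr, cfg, "control", 2, "histone")
  doms <- tr$truth[tr$truth$kind == "broad_domain"]
  cm <- count_matrix(list(a = f1, b = f2), doms)
  nt <- normalization_table(cm)
  t1 <- scale_track(compute_coverage(f1, tr$layout, 1000), nt$final_scale[1])
  t2 <- scale_track(compute_coverage(f2, tr$layout, 1000), nt$final_scale[2])
  v1 <- t1$values$chr1; v2 <- t2$values$chr1
  keep <- v1 + v2 > 0
  # genome-wide scaled means agree within a tight relative margin
  expect_lt(abs(mean(v1[keep]) / mean(v2[keep]) - 1), 0.05)
})

test_that("bedGraph export writes runs of non-zero bins in 0-based coords", {
  layout <- genome_layout("chr1", 35)
  tr <- binned_track(list(chr1 = c(0, 2, 2, 5)), layout, 10, "raw")
  p <- withr::local_tempfile()
  write_bedgraph(tr, p)
  lines <- readLines(p)
  expect_equal(lines, c("chr1\t10\t30\t2", "chr1\t30\t35\t5"))
})
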