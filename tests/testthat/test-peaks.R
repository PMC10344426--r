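test_that("fragment-size filter is strictly less-than", {
  gr <- GenomicRanges::GRanges("chr1", IRanges::IRanges(
    start = c(1, 1, 1, 1), width = c(100, 119, 120, 150)))
  kept <- filter_fragment_size(gr, max_len = 120)
  expect_equal(GenomicRanges::width(kept), c(100, 119))
  all_long <- GenomicRanges::GRanges("chr1",
                                     IRanges::IRanges(1, width = 120))
  expect_length(filter_fragment_size(all_long), 0)
  # FragmentSet wrapper preserved
  fs <- fragment_set(gr, "s1")
  expect_s3_class(filter_fragment_size(fs), "FragmentSet")
  expect_length(filter_fragment_size(fs), 2)
})

test_that("peak caller controls false discoveries on flat background", {
  layout <- genome_layout("chr1", 5e5)
  set.seed(10)
  fdp <- replicate(20, {
    n <- rpois(1, 0.02 * 5e5)
    frags <- GenomicRanges::GRanges(
      "chr1", IRanges::IRanges(sample.int(5e5 - 120, n, replace = TRUE),
                               width = 80))
    pk <- call_peaks_poisson(frags, layout, q_threshold = 0.05)
    length(pk) > 0
  })
  # under the null, most replicates yield no peaks at all
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 20))
})

test_that("a planted spike yields exactly one peak with its summit inside", {
  layout <- genome_layout("chr1", 1e6)
  set.seed(4)
  n_bg <- rpois(1, 0.02 * 1e6)
  bg <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(sample.int(1e6 - 120, n_bg, replace = TRUE),
                             width = 80))
  spike_start <- 500001; spike_end <- 500500
  n_sp <- rpois(1, 0.02 * 20 * 500)
  sp <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(spike_start +
                               sample.int(500 - 80, n_sp, replace = TRUE),
                             width = 80))
  pk <- call_peaks_poisson(c(bg, sp), layout)
  spike <- GenomicRanges::GRanges("chr1",
                                  IRanges::IRanges(spike_start, spike_end))
  expect_equal(sum(IRanges::overlapsAny(pk, spike)), 1)
  hit <- pk[IRanges::overlapsAny(pk, spike)]
  expect_gte(hit$summit, spike_start - 80)
  expect_lte(hit$summit, spike_end + 80)
  expect_length(call_peaks_poisson(GenomicRanges::GRanges(), layout), 0)
})

test_that("caller recall on planted 10x spikes is at least 0.95", {
  cfg <- sim_config(seed = 55, n_tf_peaks = 60L, tf_enrichment = 10,
                    n_domains = 0L, background_rate = 0.05,
                    dispersion = 0)
  tr <- simulate_truth(cfg)
  tf <- simulate_fragments(tr, cfg, "control", 1, "tf")
  pk <- call_peaks_poisson(filter_fragment_size(tf), tr$layout)
  planted <- tr$truth[tr$truth$kind == "tf_peak"]
  expect_gte(mean(IRanges::overlapsAny(planted, pk)), 0.95)
})

test_that("high-confidence filtering is strict at the threshold", {
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 101, 201),
                                                        width = 50))
  pk$summit <- GenomicRanges::start(pk) + 10L
  pk$neglog10_q <- c(99, 100, 101)
  kept <- filter_high_confidence(pk)
  expect_length(kept, 1)
  expect_equal(kept$neglog10_q, 101)
  expect_length(filter_high_confidence(pk[0]), 0)
})

test_that("replicate peak merging keeps the best constituent score and summit", {
  p1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  p1$summit <- 150L; p1$neglog10_q <- 150
  p2 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(180, 300))
  p2$summit <- 250L; p2$neglog10_q <- 200
  m <- merge_replicate_peaks(p1, p2)
  expect_length(m, 1)
  expect_equal(GenomicRanges::start(m), 100)
  expect_equal(GenomicRanges::end(m), 300)
  expect_equal(m$neglog10_q, 200)
  expect_equal(m$summit, 250L)
  # disjoint sets concatenate; identical sets are a fixed point
  d1 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 50))
  d1$summit <- 10L; d1$neglog10_q <- 120
  dm <- merge_replicate_peaks(d1, p2)
  expect_length(dm, 2)
  same <- merge_replicate_peaks(p1, p1)
  expect_equal(GenomicRanges::ranges(same), GenomicRanges::ranges(p1))
})

test_that("blacklist construction merges at 3 kb and unions extras", {
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 2101), width = 100))
  pk$summit <- GenomicRanges::start(pk); pk$neglog10_q <- c(150, 150)
  bl <- build_blacklist(pk)          # 2 kb apart -> one region
  expect_length(bl, 1)
  pk4 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(1, 4101), width = 100))
  pk4$summit <- GenomicRanges::start(pk4); pk4$neglog10_q <- c(150, 150)
  expect_length(build_blacklist(pk4), 2)  # 4 kb apart stays split
  lowq <- pk
  lowq$neglog10_q <- c(50, 150)
  expect_length(build_blacklist(lowq), 1)  # low-confidence peak dropped first
  expect_length(build_blacklist(pk[0]), 0)
  extra <- GenomicRanges::GRanges("chr2", IRanges::IRanges(1, 1000))
  expect_length(build_blacklist(pk, extra), 2)
})

test_that("blacklisting removes >=1 bp overlaps and keeps abutting peaks", {
  bl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(101, 200))
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(c(150, 201, 1),
                                                        c(160, 300, 100)))
  pk$neglog10_q <- rep(150, 3)
  kept <- apply_blacklist(pk, bl)
  expect_length(kept, 2)              # inside removed, abutting kept
  expect_equal(GenomicRanges::start(kept), c(201, 1))
  # filtering order does not matter (both are pure filters)
  a <- filter_high_confidence(apply_blacklist(pk, bl), 100)
  b <- apply_blacklist(filter_high_confidence(pk, 100), bl)
  expect_equal(GenomicRanges::ranges(a), GenomicRanges::ranges(b))
})

test_that("shuffle preserves the region count and length multiset exactly", {
  layout <- toy_layout(2, 2e5)
  pk <- random_intervals(40, layout, max_width = 900, seed = 12)
  sh1 <- shuffle_peaks(pk, layout, seed = 99)
  sh2 <- shuffle_peaks(pk, layout, seed = 99)
  expect_length(sh1, length(pk))
  expect_equal(sort(GenomicRanges::width(sh1)),
               sort(GenomicRanges::width(pk)))
  expect_identical(as.data.frame(sh1), as.data.frame(sh2))
  expect_length(GenomicRanges::reduce(sh1, min.gapwidth = 0), length(sh1))
  excl <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1.9e5))
  sh3 <- shuffle_peaks(pk, layout, exclude_regions = excl, seed = 5)
  expect_false(any(IRanges::overlapsAny(sh3, excl)))
})

test_that("shuffled placements are uniform over the chromosome", {
  layout <- genome_layout("chr1", 1e6)
  pk <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 1000))
  starts <- vapply(1:1000, function(s) {
    GenomicRanges::start(shuffle_peaks(pk, layout, seed = s))
  }, numeric(1))
  bins <- cut(starts, breaks = seq(0, 1e6, length.out = 11))
  expect_gt(stats::chisq.test(table(bins))$p.value, 0.01)
})
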