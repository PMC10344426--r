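make_fs <- function(gr, id, cond, rep = 1L) {
  fragment_set(gr, sample_id = id, condition = cond, replicate = rep,
               target = "histone")
}

test_that("window grids tile chromosomes at the given step", {
  layout <- genome_layout("chr1", 10000)
  fs <- make_fs(GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 300)),
                "s1", "control")
  sc <- window_scan(list(fs), layout, window = 500, step = 100)
  expect_length(sc$windows, 96)        # floor((10000-500)/100) + 1
  expect_true(all(GenomicRanges::width(sc$windows) == 500))
  short <- genome_layout(c("chr1", "tiny"), c(10000, 300))
  expect_warning(sc2 <- window_scan(list(fs), short, 500, 100), "shorter")
  expect_length(sc2$windows, 96)
})

test_that("window counts equal brute-force overlap counting", {
  layout <- genome_layout("chr1", 20000)
  frags <- random_intervals(400, genome_layout("chr1", 19500),
                            max_width = 350, seed = 3)
  fs <- make_fs(frags, "s1", "control")
  sc <- window_scan(list(fs), layout, window = 500, step = 250)
  expect_equal(as.numeric(sc$counts[, 1]),
               oracle_region_counts(frags, sc$windows))
})

test_that("identical data in both conditions yields no calls", {
  layout <- genome_layout("chr1", 50000)
  frags <- random_intervals(2000, genome_layout("chr1", 49500),
                            max_width = 300, seed = 5)
  fsets <- list(make_fs(frags, "c1", "control", 1L),
                make_fs(frags, "c2", "control", 2L),
                make_fs(frags, "m1", "mutant", 1L),
                make_fs(frags, "m2", "mutant", 2L))
  sc <- window_scan(fsets, layout)
  tab <- test_windows(sc, rep(1, 4), "control", "mutant")
  expect_true(all(tab$direction == "ns"))
  expect_true(all(tab$log2fc == 0))
  expect_error(test_windows(sc, rep(1, 4), "control", "missing"), "label")
})

test_that("null NB data keeps the empirical FDR at the nominal level", {
  set.seed(42)
  win <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, 5e3 * 100, by = 100), width = 500))
  fdp <- replicate(10, {
    cnt <- matrix(rnbinom(5e3 * 4, size = 1 / 0.1, mu = 30), ncol = 4)
    sc <- window_scan_from_counts(win, cnt,
                                  c("control", "control", "mutant", "mutant"))
    tab <- test_windows(sc, rep(1, 4), "control", "mutant")
    sum(tab$direction != "ns") / max(1, sum(tab$tested))
  })
  expect_lte(mean(fdp), 0.05 + 2 * sqrt(0.05 * 0.95 / 10))
})

test_that("increasing a treatment count never lowers its fold change", {
  win <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 501), width = 500))
  base <- matrix(c(20, 20, 20, 20, 20, 20, 20, 20), nrow = 2)
  prev <- -Inf
  for (add in c(0, 5, 20, 80)) {
    cnt <- base
    cnt[1, 3] <- cnt[1, 3] + add
    sc <- window_scan_from_counts(win, cnt,
                                  c("control", "control", "mutant", "mutant"))
    tab <- test_windows(sc, rep(1, 4), "control", "mutant", min_count = 1)
    expect_gte(tab$log2fc[1], prev)
    prev <- tab$log2fc[1]
  }
})

test_that("q-values depend only on the ratios of the scale factors", {
  set.seed(8)
  win <- GenomicRanges::GRanges(
    "chr1", IRanges::IRanges(seq(1, 500 * 100, by = 100), width = 500))
  cnt <- matrix(rnbinom(500 * 4, size = 50, mu = 40), ncol = 4)
  sc <- window_scan_from_counts(win, cnt,
                                c("control", "control", "mutant", "mutant"))
  sf <- c(1.2, 0.8, 1.1, 0.95)
  t1 <- test_windows(sc, sf, "control", "mutant")
  t2 <- test_windows(sc, sf * 37.5, "control", "mutant")
  expect_equal(t1$qvalue, t2$qvalue)
  expect_equal(t1$log2fc, t2$log2fc)
})

test_that("bound flags follow >=1 bp overlap with half-open boundaries", {
  win <- GenomicRanges::GRanges("chr1",
                                IRanges::IRanges(c(1, 1001), width = 500))
  tab <- data.frame(chrom = "chr1", start = c(1, 1001),
                    end = c(500, 1500), qvalue = c(0.01, 0.5),
                    log2fc = c(-2, 0), tested = TRUE,
                    direction = c("down", "ns"))
  pk_abut <- GenomicRanges::GRanges("chr1", IRanges::IRanges(501, 900))
  expect_equal(mark_bound(tab, pk_abut)$bound, c(FALSE, FALSE))
  pk_in <- GenomicRanges::GRanges("chr1", IRanges::IRanges(100, 200))
  expect_equal(mark_bound(tab, pk_in)$bound, c(TRUE, FALSE))
})

test_that("kb summaries merge windows before accounting", {
  tab <- data.frame(
    chrom = "chr1",
    start = seq(1, by = 1000, length.out = 10),
    end = seq(500, by = 1000, length.out = 10),
    log2fc = c(rep(-1.5, 4), rep(0.5, 6)),
    qvalue = rep(0.01, 10),
    tested = TRUE)
  s <- summarize_fc(tab)
  expect_equal(s$total_sig_kb[s$stratum == "all"], 5)
  expect_equal(s$down_kb[s$stratum == "all"], 2)
  expect_equal(s$down_pct[s$stratum == "all"], 40)
  # overlapping significant windows collapse into one region's kb
  tab2 <- data.frame(chrom = "chr1", start = c(1, 101), end = c(500, 600),
                     log2fc = c(-2, -2), qvalue = c(0.01, 0.01),
                     tested = TRUE)
  s2 <- summarize_fc(tab2)
  expect_equal(s2$total_sig_kb[s2$stratum == "all"], 0.6)
  none <- summarize_fc(data.frame(chrom = "chr1", start = 1, end = 500,
                                  log2fc = 0, qvalue = 0.9, tested = TRUE))
  expect_true(all(none[none$stratum == "all", -1] == 0))
})

test_that("volcano tables round-trip and put q = 0.05 at 1.301", {
  tab <- data.frame(chrom = "chr1", start = c(1, 101), end = c(500, 600),
                    log2fc = c(-2, 1), qvalue = c(0.05, 1),
                    tested = TRUE, bound = c(TRUE, FALSE))
  p <- withr::local_tempfile()
  v <- volcano_table(tab, p)
  expect_equal(round(v$neglog10_q[1], 3), 1.301)
  expect_equal(v$neglog10_q[2], 0)
  back <- utils::read.table(p, header = TRUE, sep = "\t")
  expect_equal(back$log2fc, v$log2fc)
  expect_equal(back$bound, v$bound)
})

test_that("planted decreases are detected and concentrate in bound windows", {
  cfg <- sim_config(seed = 77, background_rate = 0.073, n_tf_peaks = 80L,
                    tf_peak_width = 1500L, low_level_fraction = 1,
                    fraction_down = 0.8, n_domains = 6L,
                    n_chroms = 1L, chrom_length = 2e6)
  sim <- sim_histone_samples(cfg)
  tr <- sim$truth
  doms <- filter_domains(call_islands(
    concat_ctrl(sim$samples, "control"), tr$layout))
  nt <- normalization_table(count_matrix(sim$samples, doms))
  sc <- window_scan(sim$samples, tr$layout)
  tab <- test_windows(sc, stats::setNames(nt$final_scale, nt$sample_id),
                      "control", "mutant")
  tab <- mark_bound(tab, tr$truth[tr$truth$kind == "tf_peak"])
  down <- tr$truth[tr$truth$kind == "low_level_mark" & tr$truth$fc_mutant < 1]
  sig_down <- tab$direction == "down" & tab$log2fc < -1
  hit <- GenomicRanges::GRanges(tab$chrom[sig_down],
                                IRanges::IRanges(tab$start[sig_down],
                                                 tab$end[sig_down]))
  expect_gte(mean(IRanges::overlapsAny(down, hit)), 0.8)
  s <- summarize_fc(tab)
  expect_gt(s$down_pct[s$stratum == "bound"],
            s$down_pct[s$stratum == "unbound"])
})
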