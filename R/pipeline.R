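#' Pipeline configuration
#'
#' Collects every tunable parameter of the end-to-end analysis with the
#' pipeline's standard defaults: 500 bp differential windows stepped by
#' 100 bp at q < 0.05 and fold-change cutoff 2, peak confidence
#' `-log10(q) > 100`, H3K9me3 blacklist merge gap 3000 bp, island calling at
#' w = 500 / gap = 2000 / egf = 0.7, domain filters score > 500 and
#' length > 3000 with a 10 kb cross-replicate merge, TF fragment cap 120 bp,
#' and midpoint-mode 500 bp bin density on depth-matched fragments.
#'
#' @param seed Master seed for the whole run.
#' @param sim A [sim_config()] (defaults to `sim_config(seed = seed)` with
#'   mild per-sample depth differences).
#' @param window,step Differential window size and step (bp).
#' @param alpha Q-value cutoff for differential windows.
#' @param fc_threshold Fold-change threshold for the kb summaries.
#' @param min_count Minimum pooled normalized count for window testing.
#' @param peak_q Q-value cutoff of the narrow-peak caller.
#' @param peak_confidence Strict `-log10(q)` confidence threshold.
#' @param blacklist_gap Merge gap for the heterochromatin blacklist (bp).
#' @param island_w,island_gap,island_egf Island-calling parameters.
#' @param domain_min_score,domain_min_length Domain filters (strict).
#' @param domain_merge_gap Cross-replicate domain merge distance (bp).
#' @param fragment_cap Exclusive TF fragment-length cutoff (bp).
#' @param density_bin Bin width for the read-density comparison (bp).
#' @param subsample_n Fragments per condition for density; `NULL` uses the
#'   smallest condition total.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L,
                            sim = NULL,
                            window = 500, step = 100,
                            alpha = 0.05, fc_threshold = 2, min_count = 10,
                            peak_q = 0.05, peak_confidence = 100,
                            blacklist_gap = 3000,
                            island_w = 500, island_gap = 2000,
                            island_egf = 0.7,
                            domain_min_score = 500, domain_min_length = 3000,
                            domain_merge_gap = 10000,
                            fragment_cap = 120,
                            density_bin = 500, subsample_n = NULL) {
  if (is.null(sim)) {
    # study-emulating defaults: per-bp depth matching the 10M-fragment
    # subsampling of a fly-sized genome, kb-scale bound regions, replicate
    # BCV ~0.14, and mild depth differences between samples
    sim <- sim_config(
      seed = seed,
      background_rate = 0.073,
      tf_peak_width = 1500,
      depth_multiplier = c(control_1_histone = 1, control_2_histone = 0.85,
                           mutant_1_histone = 1.15, mutant_2_histone = 0.9,
                           control_1_tf = 1, control_2_tf = 1))
  }
  cfg <- as.list(environment())
  class(cfg) <- "pipeline_config"
  cfg
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys map to [pipeline_config()] arguments; a nested `sim` map
#' is forwarded to [sim_config()]. Unknown keys are rejected.
#'
#' @param path YAML file path.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- setdiff(names(formals(pipeline_config)), "sim")
  bad <- setdiff(names(raw), c(known, "sim"))
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(raw$sim)) {
    sim_known <- names(formals(sim_config))
    sim_bad <- setdiff(names(raw$sim), sim_known)
    if (length(sim_bad)) {
      stop("unknown sim config keys: ", paste(sim_bad, collapse = ", "))
    }
    if (!is.null(raw$sim$depth_multiplier)) {
      raw$sim$depth_multiplier <- unlist(raw$sim$depth_multiplier)
    }
    raw$sim <- do.call(sim_config, raw$sim)
  }
  do.call(pipeline_config, raw)
}

#' Run the end-to-end synthetic analysis
#'
#' Simulates the experiment, then executes every stage: TF fragment-size
#' filtering, per-replicate peak calling with confidence filtering and
#' replicate merging, matched shuffled background, gene classification and
#' peak annotation with bound-gene fractions, reads-in-peaks TMM
#' normalization with final scale factors, the 500 bp sliding-window
#' differential scan with bound/unbound kb summaries and volcano export,
#' broad-domain calling/filtering/merging with the peak-vs-domain coverage
#' ratio, and the depth-matched bin-density comparison. Every table is
#' written as TSV/BED under `out_dir` and the run is deterministic given the
#' seed.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; overwritten files replaced).
#' @return Invisibly, a list with all in-memory results (`report` holds the
#'   headline numbers).
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "pipeline.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  file.create(log_path)
  logf("config", "seed=", config$seed, " window=", config$window,
       " step=", config$step, " alpha=", config$alpha,
       " fc=", config$fc_threshold, " peak_confidence=",
       config$peak_confidence)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE)
    })
  }

  ## simulate
  sim <- stage("simulate", simulate_experiment(config$sim))
  write_truth(sim$truth, file.path(out_dir, "truth"))
  layout <- sim$truth$layout
  logf("simulate", length(sim$histone), " histone + ", length(sim$tf),
       " TF samples")

  ## TF peaks
  res <- stage("callpeaks", {
    tf_filt <- lapply(sim$tf, filter_fragment_size,
                      max_len = config$fragment_cap)
    called <- lapply(tf_filt, call_peaks_poisson, layout = layout,
                     q_threshold = config$peak_q)
    hc <- lapply(called, filter_high_confidence,
                 min_neglog10_q = config$peak_confidence)
    peaks <- if (length(hc) >= 2) {
      merge_replicate_peaks(hc[[1]], hc[[2]])
    } else hc[[1]]
    list(tf_filt = tf_filt, called = called, peaks = peaks)
  })
  peaks <- res$peaks
  pk_bed <- GenomicRanges::granges(peaks)
  pk_bed$name <- sprintf("peak%04d", seq_along(peaks))
  pk_bed$score <- peaks$neglog10_q
  write_bed(pk_bed, file.path(out_dir, "tf_peaks.bed"))
  logf("callpeaks", length(peaks), " merged high-confidence peaks")

  shuffled <- stage("shuffle", shuffle_peaks(
    peaks, layout, exclude_regions = peaks,
    seed = derive_seed(config$seed, "shuffle")))
  write_bed(shuffled, file.path(out_dir, "shuffled_peaks.bed"))

  ## annotation and gene classes
  ann <- stage("annotate", {
    classes <- classify_genes(sim$de_table)
    pa <- annotate_peaks(peaks, sim$truth$genes)
    sa <- annotate_peaks(shuffled, sim$truth$genes)
    dist <- genomic_distribution(pa)
    frac <- vapply(c("nb_enriched", "immINP_enriched", "invariant"),
                   function(cl) bound_gene_fraction(pa, classes, cl),
                   numeric(1))
    frac_shuf <- vapply(c("nb_enriched", "immINP_enriched", "invariant"),
                        function(cl) bound_gene_fraction(sa, classes, cl),
                        numeric(1))
    shuffled_overlap <- peakset_overlap_fraction(shuffled, peaks)
    list(classes = classes, peak_annotation = pa, distribution = dist,
         bound_fraction = frac, bound_fraction_shuffled = frac_shuf,
         shuffled_overlap_pct = shuffled_overlap)
  })
  utils::write.table(ann$peak_annotation,
                     file.path(out_dir, "peak_annotation.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$classes, file.path(out_dir, "gene_classes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ann$distribution,
                     file.path(out_dir, "genomic_distribution.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  ## normalization: reads-in-peaks TMM on the histone mark
  ctrl_label <- config$sim$conditions[1]
  mut_label <- config$sim$conditions[2]
  norm <- stage("normalize", {
    ctrl <- sim$histone[vapply(sim$histone, function(f)
      f$condition == ctrl_label, logical(1))]
    pooled <- concat_gr(lapply(ctrl, as_fragments))
    # reads-in-peaks regions for a broad mark are its called strong peaks,
    # i.e. the score/length-filtered islands (weak peak-local enrichment is
    # below peak-calling confidence and must not steer normalization)
    mark_peaks <- filter_domains(
      call_islands(pooled, layout, w = config$island_w,
                   gap = config$island_gap, egf = config$island_egf),
      min_score = config$domain_min_score,
      min_length = config$domain_min_length)
    cm <- count_matrix(sim$histone, mark_peaks)
    nt <- normalization_table(cm)
    list(mark_peaks = mark_peaks, counts = cm, table = nt)
  })
  utils::write.table(norm$table, file.path(out_dir, "normalization.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("normalize", nrow(norm$table), " samples; TMM factors ",
       paste(signif(norm$table$tmm_factor, 4), collapse = ","))

  ## differential windows
  diff <- stage("diffwindows", {
    scan <- window_scan(sim$histone, layout, window = config$window,
                        step = config$step)
    sf <- stats::setNames(norm$table$final_scale, norm$table$sample_id)
    tab <- test_windows(scan, sf, control = ctrl_label,
                        treatment = mut_label, alpha = config$alpha,
                        min_count = config$min_count)
    tab <- mark_bound(tab, peaks)
    summ <- summarize_fc(tab, fc_threshold = config$fc_threshold,
                         alpha = config$alpha)
    list(table = tab, summary = summ)
  })
  utils::write.table(diff$table, file.path(out_dir, "diff_windows.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(diff$summary, file.path(out_dir, "diff_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  volcano_table(diff$table, file.path(out_dir, "volcano.tsv"))
  logf("diffwindows", sum(diff$table$tested), " tested windows; ",
       "dispersion=", signif(attr(diff$table, "dispersion"), 4))

  ## broad domains and coverage ratio
  dom <- stage("domains", {
    ctrl <- sim$histone[vapply(sim$histone, function(f)
      f$condition == ctrl_label, logical(1))]
    per_rep <- lapply(ctrl, function(fs) {
      filter_domains(call_islands(fs, layout, w = config$island_w,
                                  gap = config$island_gap,
                                  egf = config$island_egf),
                     min_score = config$domain_min_score,
                     min_length = config$domain_min_length)
    })
    domains <- if (length(per_rep) >= 2) {
      merge_domains(per_rep[[1]], per_rep[[2]],
                    max_gap = config$domain_merge_gap)
    } else per_rep[[1]]
    pk_out <- peaks_outside_domains(peaks, domains)
    pc <- region_coverage(ctrl, pk_out, mode = "midpoint")
    dc <- region_coverage(ctrl, domains, mode = "midpoint")
    cr <- coverage_ratio(pc, dc)
    list(domains = domains, peak_cov = pc, domain_cov = dc, ratio = cr)
  })
  dom_bed <- GenomicRanges::granges(dom$domains)
  dom_bed$name <- sprintf("domain%03d", seq_along(dom$domains))
  dom_bed$score <- dom$domains$score
  write_bed(dom_bed, file.path(out_dir, "pc_domains.bed"))
  utils::write.table(dom$peak_cov, file.path(out_dir, "peak_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(dom$domain_cov,
                     file.path(out_dir, "domain_coverage.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("domains", length(dom$domains), " domains; coverage ratio ",
       signif(dom$ratio$ratio, 4))

  ## depth-matched bin density
  dens <- stage("density", {
    by_cond <- lapply(c(ctrl_label, mut_label), function(cc) {
      fr <- sim$histone[vapply(sim$histone, function(f)
        f$condition == cc, logical(1))]
      concat_gr(lapply(fr, as_fragments))
    })
    names(by_cond) <- c(ctrl_label, mut_label)
    n <- config$subsample_n %||% min(lengths(by_cond))
    sub <- lapply(names(by_cond), function(cc) {
      subsample_fragments(by_cond[[cc]], n,
                          seed = derive_seed(config$seed,
                                             paste0("subsample:", cc)))
    })
    names(sub) <- names(by_cond)
    bd <- bin_density(sub, make_bins(layout, config$density_bin), peaks)
    c(bd, list(n = n))
  })
  utils::write.table(dens$summary, file.path(out_dir, "bin_density_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("density", dens$n, " fragments per condition")

  ## report
  bs <- diff$summary
  report <- list(
    n_peaks = length(peaks),
    promoter_pct = 100 * ann$distribution$fraction[
      ann$distribution$category == "promoter"],
    regulatory_pct = 100 * sum(ann$distribution$fraction[
      ann$distribution$category %in% c("intronic", "intergenic")]),
    nb_bound_pct = unname(ann$bound_fraction["nb_enriched"]),
    nb_bound_shuffled_pct = unname(ann$bound_fraction_shuffled["nb_enriched"]),
    invariant_bound_pct = unname(ann$bound_fraction["invariant"]),
    total_sig_kb = bs$total_sig_kb[bs$stratum == "all"],
    bound_down2x_pct = bs$down_pct[bs$stratum == "bound"],
    unbound_down2x_pct = bs$down_pct[bs$stratum == "unbound"],
    n_domains = length(dom$domains),
    coverage_ratio = dom$ratio$ratio)
  rep_df <- data.frame(metric = names(report),
                       value = unlist(report), row.names = NULL)
  utils::write.table(rep_df, file.path(out_dir, "report.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  logf("report", "done")

  invisible(list(sim = sim, peaks = peaks, shuffled = shuffled,
                 annotation = ann, normalization = norm, diff = diff,
                 domains = dom, density = dens, report = report))
}
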