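# crquant

Quantitative analysis of CUT&RUN data for detecting **low-level histone-mark
changes** between conditions — the regime where a transcription factor
deposits or maintains a repressive mark (H3K27me3) at its binding sites at
levels far below canonical Polycomb domains, and where losing the factor
erodes precisely that low-level signal.

The package is aimed at epigenomics analysts who have per-sample fragment
intervals (BED) from a CUT&RUN experiment with two conditions and
replicates, and who need the full quantification chain without spike-in
scaling:

* **TMM-on-reads-in-peaks normalization** with the final per-sample scale
  factor `1e6 / (normFactor x reads_in_peaks)`;
* **500 bp sliding-window differential enrichment** with an exact
  negative-binomial conditional test, BH correction, and kb-fraction
  summaries stratified by transcription-factor binding;
* **SICER-style broad-domain (Polycomb domain) calling** with
  score > 500 / length > 3 kb filters and 10 kb cross-replicate merging;
* **coverage-ratio comparison** of narrow peaks against broad domains
  (reads per bp, averaged across replicates);
* **depth-matched genome-bin density statistics** (exact subsampling, bound
  vs unbound strata);
* a substitute **narrow-peak caller** with strict high-confidence
  filtering (`-log10 q > 100`), H3K9me3 blacklisting (`merge -d 3000`),
  and **matched shuffled backgrounds** (same region count, same length
  multiset);
* **HOMER-style peak annotation** (promoter/tts/exonic/intronic/intergenic
  at the summit, nearest-TSS gene assignment) and **gene-class binding
  fractions** against an scRNA-seq-derived classification
  (|FC| > 2 & padj < 0.05 differential, |FC| < 2 invariant);
* a **synthetic fragment simulator** with planted ground truth (peaks,
  low-level mark regions with condition fold changes, broad domains, gene
  classes) so the whole pipeline is testable end to end.

## The model in brief

Window counts are modelled as negative binomial, `Var(y) = mu(1 + phi mu)`.
Per-sample scale factors come from TMM on a reads-in-peaks matrix (for a
broad mark, the "peaks" are its strong filtered islands, i.e. the Polycomb
domains — regions whose signal does not change and can anchor the scale).
For each 500 bp window, replicate counts are normalized, pooled per
condition, and tested conditionally on the pooled total: under the null
both pooled counts are NB with means proportional to replicate numbers and
size `n_c / phi`, with `phi` estimated once across windows by method of
moments. Significant windows (BH q < 0.05) are merged into regions before
kilobase accounting, and classified by direction and by a twofold-change
threshold.

Island calling tests each 500 bp window against
`lambda = N w / (egf G)` (Poisson, eligibility at upper-tail p < 0.2),
clusters eligible windows within 2 kb, and scores islands by summed Poisson
surprisal in nats.

## Worked example

```r
library(crquant)

cfg <- pipeline_config(seed = 1)       # simulate + analyse, one seed
res <- run_pipeline(cfg, "crquant-demo")
str(res$report)
```

On the default simulated study (2 x 2.5 Mb genome, two conditions x two
replicates of an H3K27me3-like mark, one sub-120 bp transcription-factor
sample, 74% of planted peaks at neuroblast-gene promoters, a 2.5-fold
mark loss planted at 75% of the peak-local mark regions) this prints:

```
List of 11
 $ n_peaks              : int 101
 $ promoter_pct         : num 43.6
 $ regulatory_pct       : num 53.5
 $ nb_bound_pct         : num 74.4
 $ nb_bound_shuffled_pct: num 30
 $ invariant_bound_pct  : num 16.7
 $ total_sig_kb         : num 84
 $ bound_down2x_pct     : num 81.9
 $ unbound_down2x_pct   : num 5.05
 $ n_domains            : int 10
 $ coverage_ratio       : num 4.22
```

Reading these: 101 high-confidence merged peaks were called; 74.4% of
neuroblast-class genes have an assigned peak versus 30% for the matched
shuffled control (the planted fraction is 0.74); of the significant
differential kilobases, 81.9% of the factor-bound kb show a more than
twofold H3K27me3 decrease in the mutant versus 5.1% of unbound kb — the
planted bound-specific loss; 10 broad domains were recovered (12 planted;
two fall below the strict score/length filters at this depth), and domains
carry 4.2-fold more mark coverage than peaks (planted 8x domains over a
mix of 3x-marked and unmarked peaks). Every intermediate lands in the
output directory as BED/TSV (`diff_windows.tsv`, `pc_domains.bed`,
`volcano.tsv`, `report.tsv`, ...), and a rerun with the same config is
byte-identical.

The stages are equally usable on real data: read fragments with
`read_bed()` into `fragment_set()`s, then call `filter_fragment_size()`,
`call_peaks_poisson()`/`filter_high_confidence()`, `count_matrix()` +
`normalization_table()`, `window_scan()` + `test_windows()` +
`summarize_fc()`, `call_islands()` + `filter_domains()` +
`merge_domains()`, `region_coverage()` + `coverage_ratio()`, and
`bin_density()` directly.

## Package layout

```
R/                  genome I/O, simulator, coverage/normalization, peaks,
                    annotation, differential windows, domains, bin density,
                    pipeline orchestration
tests/testthat/     unit + property tests per module, acceptance suite
scripts/            acceptance.R
vignettes/          methods vignette (model, parameters, design choices)
```
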