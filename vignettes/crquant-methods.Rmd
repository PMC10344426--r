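---
title: "Methods: quantifying low-level histone-mark changes in CUT&RUN data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying low-level histone-mark changes in CUT&RUN data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crquant)
```

## The problem

CUT&RUN profiles protein-DNA interactions with very low background, which
makes it attractive for detecting *quantitative* changes in histone marks —
including low-level enrichment far below the classical "peak" regime. The
motivating biology is a *Drosophila* neural stem cell (type II neuroblast)
system in which a transcription factor promotes low-level H3K27me3 at its
binding sites, an order of magnitude below canonical Polycomb domains, and
loss of the factor erodes precisely that low-level signal. Detecting such
changes requires (i) normalization that does not assume equal global signal,
(ii) a differential test over sliding windows rather than called peaks,
(iii) broad-domain calling to separate the Polycomb regime from the
peak-local regime, and (iv) careful matched controls.

`crquant` implements that quantification pipeline end to end, together with
a synthetic fragment simulator with planted ground truth so that every stage
is testable without any sequencing data.

## Normalization: TMM on reads in peaks

Spike-in-free scaling uses the trimmed mean of M-values computed on a
regions-by-samples count matrix, where the regions are the mark's called
strong peaks. For a broad mark such as H3K27me3 those regions are its
score- and length-filtered islands (the Polycomb domains): low-level
peak-local enrichment sits below peak-calling confidence against an IgG
control and therefore must not steer the normalization. This matters: if
regions whose signal genuinely changes between conditions dominate the
region set, the trimmed mean normalizes *to the change* and inverts the
genome-wide comparison. With domains as the region set, the factors absorb
depth and composition differences while the unchanged broad signal anchors
the scale.

The per-sample factor applied to tracks and window counts is

```
final_scale = 1e6 / (tmm_factor * reads_in_peaks)
```

`tmm_factors()` follows the reference implementation's conventions exactly:
the reference sample is the one whose upper quartile of library-scaled
counts is closest to the mean upper quartile; M and A values are computed
over regions with nonzero counts in both samples; 30% of M and 5% of A are
trimmed from each tail; the factor is the inverse-variance weighted mean of
the retained M (binomial delta-method weights); factors are rescaled to
geometric mean 1. The test suite checks equality against an independently
coded brute-force oracle and against `edgeR::calcNormFactors` to 1e-6.

## Differential sliding windows

`window_scan()` tiles the genome with 500 bp windows every 100 bp and counts
fragments by any (>= 1 bp) overlap. `test_windows()` then

1. multiplies each sample's counts by its final scale factor, after
   renormalizing the scale vector to geometric mean 1 — only the *ratios*
   of the factors can matter to a differential test, and this makes that
   invariance exact;
2. pools replicate counts within condition and applies an exact
   negative-binomial conditional test: under the null the two pooled counts
   are NB with means proportional to the replicate numbers and size
   `n_c / phi`; conditional on their total, the two-sided p-value sums all
   outcomes no more probable than the observed one (the phi = 0 limit is a
   conditional binomial test; with one replicate per condition a G-test is
   used);
3. estimates the common dispersion phi across windows by method of moments
   on within-condition replicate means and variances, with the squared-mean
   denominator bias-corrected by `var/n`;
4. BH-adjusts p over tested windows (pooled normalized count >= 10;
   windows below that are reported untested) and calls direction at
   q < 0.05. Fold changes use normalized condition means with a pseudocount
   of 0.5 — for reporting only, never inside the test.

The conditional exact test is deliberately conservative: in the null
simulation prescribed by the acceptance suite (identical NB law in both
conditions, dispersion 0.1, 2 + 2 replicates, 10,000 windows, 20
repetitions) the empirical false discovery proportion is essentially zero,
well inside the nominal 5%.

`summarize_fc()` merges significant windows into maximal runs before any kb
accounting (the natural unit is region kilobases, not window counts, since
adjacent sliding windows share fragments), then reports total significant
kb and the kb with more than twofold increase or decrease, overall and
stratified by overlap with a reference transcription-factor peak set.

## Narrow peaks, confidence filtering, and matched controls

`call_peaks_poisson()` is a documented substitute caller, not a MACS2
reimplementation: fixed 150 bp windows, Poisson test against
`lambda = max(genome-wide, 1 kb local, 10 kb local)`, BH correction,
joining of adjacent significant windows, summit at the coverage maximum.
One design point deserves emphasis: the local lambdas are running means
computed after masking windows that are already clearly enriched against
the genome-wide rate (p < 0.01). Without that masking a peak inflates its
own local background — for strong CUT&RUN peaks spanning several windows
the self-contamination is large enough that the high-confidence regime
(`-log10 q > 100`, applied strictly) would be unreachable at any realistic
enrichment.

Post-processing follows the study's conventions exactly: strict `< 120` bp
fragment filtering for transcription-factor samples, strict `> 100`
confidence filtering, replicate merging at gap 0 (merged score = max of
constituents, a conservative choice the source text leaves open),
heterochromatin blacklists built by merging high-confidence H3K9me3 peaks
at gap 3000 bp, and matched shuffled backgrounds that preserve the region
count and the exact multiset of region lengths, placed uniformly and
non-overlapping, with a retry cap of 1000 per region.

## Broad domains and the coverage-ratio comparison

`call_islands()` is a SICER-style caller: 500 bp windows, expected count
`lambda = N * w / (egf * G)` with effective genome fraction 0.7, window
eligibility at Poisson upper-tail p < 0.2 (the conventional window
threshold), clustering of eligible windows at gaps up to 2000 bp, and
island scores as summed Poisson surprisal, `-ln P(count; lambda)`, in nats.
Domains keep islands with score strictly above 500 and length strictly
above 3000 bp, then merge across replicates within 10 kb (scores add). The
pipeline fixes filter-then-merge, matching the order of the source
procedure; the suite tests explicitly that the reverse order differs
(merging can rescue sub-threshold lengths).

The coverage comparison divides the mean per-bp coverage of domains by that
of transcription-factor peaks lying entirely outside domains.
`region_coverage()` offers two counting modes: `"overlap"` (the
featureCounts convention — a fragment counts in every region it touches)
and `"midpoint"` (each fragment counts in at most one region). The pipeline
uses midpoint mode for this ratio because overlap counting inflates a
600-1500 bp peak's apparent coverage by roughly `(width + fraglen)/width`
while leaving 20 kb domains nearly untouched, which would bias the
domain-to-peak ratio downward by 30% or more purely as a measurement
artifact. With midpoint counting the planted 3-fold contrast is recovered
as 3.0 within Monte-Carlo error.

## Bin density with depth matching

`bin_density()` compares per-500-bp-bin read counts between conditions
after `subsample_fragments()` has drawn exactly equal fragment numbers
(uniform, without replacement, seed-deterministic). The default
fragment-to-bin rule is again midpoint assignment, so per-condition totals
are conserved and "reads per bin" distributions are directly comparable;
any-overlap counting is available as an option. Short terminal bins are
kept in the table but excluded from the summaries (their width biases the
density). A practical caveat the simulator makes visible: depth matching
compares *library shares*, so if the changed regions carry a non-negligible
fraction of the library, subsampling itself shifts the unchanged stratum.
The unbound stratum is only expected to be indistinguishable when bound
regions hold a small percentage of fragments — which is the situation in a
real genome, where bound regions are a tiny fraction of the total.

## The synthetic-data generator

`sim_config()` / `simulate_truth()` / `simulate_fragments()` emulate the
study's data structure: two conditions times two replicates of a histone
mark, one short-fragment transcription-factor sample, a gene set
partitioned into neuroblast-enriched / immature-INP-enriched / invariant
classes (30/20/50%), transcription-factor peaks placed in promoter windows
of neuroblast-class genes for a configurable fraction (default 0.74,
matching the bound-fraction regime the pipeline should recover), low-level
mark enrichment on a subset of those peaks with a planted mutant fold
change, and broad domains away from peaks. Fragment counts are negative
binomial with mean `background_rate x depth x enrichment` and variance
`mu(1 + phi mu)`, drawn per 500 bp tile so that overdispersion acts at a
local scale — it then appears as replicate-to-replicate window variance,
not as chromosome-length rate drifts that no real sample exhibits (an
earlier per-segment formulation produced exactly such drifts and spurious
broad islands). Fragment lengths are uniform: 50-119 bp for the
transcription factor, 150-400 bp for the histone mark; fragments that would
overrun a chromosome are redrawn. One master seed drives everything, with
per-sample substreams derived by hashing the sample identity, so adding a
sample never perturbs another.

Parameter choices that the generator fixes as its study conditions, with
their derivations:

* **background depth 0.073 fragments/bp** for the pipeline's default
  simulation — the study depth-matches histone samples to 10 million
  fragments on a ~137 Mb genome; the generator's own default stays at the
  lighter 0.02 fragments/bp toy scale (2 x 2.5 Mb genome) used by the unit
  tests;
* **dispersion phi = 0.02** — a replicate biological coefficient of
  variation of ~0.14, typical of well-controlled duplicate pools of
  dissected tissue;
* **transcription-factor peak enrichment 50x** — the signal-to-background
  regime of strong CUT&RUN factors, and the regime in which
  `-log10 q > 100` peaks exist at toy depth;
* **bound-region width 1.5 kb** in the pipeline default — merged
  replicate peak regions are kb-scale;
* **low-level mark enrichment 3x, domains 8x** — reproducing the roughly
  3-fold coverage gap between peak-local and Polycomb-domain H3K27me3;
* **mutant fold change 0.4** (a 2.5-fold loss) on 75% of the low-level
  regions by default.

What the simulator does *not* model: sequence content and mappability (no
FASTQ, no alignment), PCR duplicates, GC bias, fragment-length/ signal
interactions, and chromatin-state autocorrelation beyond the planted
regions. Passing tests therefore demonstrate the pipeline's statistical
correctness and bookkeeping on data with known truth, not robustness to
alignment artifacts.

## Numerical and degenerate-input choices

* Coordinates are 0-based half-open in every file (BED, bedGraph); in
  memory intervals live in `GRanges` (1-based closed) and conversion
  happens only at the file boundary.
* Intervals crossing chromosome ends are rejected, never clipped.
* Merging uses the `bedtools merge -d` convention: gap <= d merges, and
  bookended intervals merge at d = 0. Strand is always ignored.
* Z-score tracks use the population standard deviation over all bins of all
  chromosomes; a constant track z-scores to all zeros with a warning.
* Zero-count regions drop out of TMM (their log-ratios are not finite);
  fewer than two usable regions yields factor 1 with a warning.
* The gene classification rule is exact: differential iff |FC| > 2 and
  adjusted p < 0.05, invariant iff |FC| < 2 (p ignored), otherwise
  unclassified; |FC| = 2 to the |log2 FC|.
* The overestimated-variance t-test divides *both* group variance terms by
  the focal group's size, the convention that deliberately overestimates
  the standard error; its null p-values are stochastically larger than
  uniform, which the suite asserts by simulation.
* Peak categories are decided at the summit (midpoint fallback) with
  precedence promoter > tts > exonic > intronic > intergenic; the promoter
  window is (-1000, +100) around the TSS and the TTS window (-100, +1000),
  both strand-aware; every peak is assigned the gene with the nearest TSS.
  Positions inside a gene body count as exonic only when an exon annotation
  is supplied, otherwise intronic.
* Ties in the TMM reference-sample choice break to the lowest column index;
  ties in nearest-TSS assignment break arbitrarily but deterministically.

## Problem sizes

The default simulated study is a 2 x 2.5 Mb genome at 0.073 fragments/bp
(roughly 400-500 thousand fragments per sample, ~50,000 sliding windows),
which the full pipeline processes in well under a minute; the unit-test
fixtures are smaller still. These sizes were chosen so the whole suite and
the acceptance script run comfortably on a single CPU while keeping every
statistical regime (confidence filtering, FDR control, domain recovery)
non-degenerate.

## Known limitations

* The substitute peak caller and island caller are fixed, documented
  algorithms chosen for determinism and controlled error rates; they do not
  reproduce MACS2/GoPeaks/SICER outputs read-for-read.
* The window test uses a single common dispersion; there is no per-window
  empirical-Bayes shrinkage, so very heterogeneous dispersion landscapes
  will be tested conservatively.
* Pooling replicates within condition assumes replicate depths are
  comparable after normalization; grossly unbalanced replicates would be
  better served by a GLM.
* The `tts` category and exon-aware annotation are simplified relative to a
  full annotation hierarchy (no UTR splits).
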