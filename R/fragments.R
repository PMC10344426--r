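#' Construct a fragment set
#'
#' A fragment set holds one sample's sequenced fragments (the paired-end
#' inferred intervals, unstranded) together with its sample metadata.
#'
#' @param fragments A `GRanges` of fragment intervals.
#' @param sample_id Sample identifier.
#' @param condition Condition label (e.g. `"control"`, `"mutant"`).
#' @param replicate Replicate number (integer >= 1).
#' @param target Assay target label (e.g. `"H3K27me3"`, `"tf"`).
#' @param layout Optional `Seqinfo`; fragments are validated against it.
#' @return An object of class `FragmentSet`.
#' @export
fragment_set <- function(fragments, sample_id, condition = NA_character_,
                         replicate = 1L, target = NA_character_,
                         layout = NULL) {
  stopifnot(methods::is(fragments, "GRanges"))
  if (length(fragments) > 0) {
    validate_intervals(fragments, layout, what = "fragment")
  }
  if (!is.null(layout)) fragments <- set_layout(fragments, layout)
  structure(
    list(fragments = fragments, sample_id = as.character(sample_id),
         condition = as.character(condition),
         replicate = as.integer(replicate), target = as.character(target)),
    class = "FragmentSet")
}

#' @export
print.FragmentSet <- function(x, ...) {
  cat(sprintf("FragmentSet '%s' (%s, rep %d, target %s): %d fragments\n",
              x$sample_id, x$condition, x$replicate, x$target,
              length(x$fragments)))
  invisible(x)
}

#' @export
length.FragmentSet <- function(x) length(x$fragments)

# Accept either a FragmentSet or a bare GRanges wherever fragments are counted.
as_fragments <- function(x) {
  if (inherits(x, "FragmentSet")) x$fragments
  else if (methods::is(x, "GRanges")) x
  else stop("expected a FragmentSet or GRanges")
}

#' Filter fragments by size
#'
#' Keeps fragments strictly shorter than `max_len` bp. Transcription-factor
#' CUT&RUN fragments are sub-nucleosomal; the conventional cutoff keeps only
#' fragments < 120 bp.
#'
#' @param fs A `FragmentSet` (or `GRanges`).
#' @param max_len Exclusive upper bound on fragment length (default 120).
#' @return Object of the same type with only fragments of length < `max_len`.
#' @export
filter_fragment_size <- function(fs, max_len = 120) {
  gr <- as_fragments(fs)
  keep <- GenomicRanges::width(gr) < max_len
  if (inherits(fs, "FragmentSet")) {
    fs$fragments <- gr[keep]
    fs
  } else {
    gr[keep]
  }
}

#' Subsample fragments without replacement
#'
#' Uniform sample of exactly `n` fragments, deterministic for a given seed.
#' Used to depth-match samples before bin-density comparison.
#'
#' @param fs A `FragmentSet` (or `GRanges`).
#' @param n Number of fragments to keep; must not exceed the set size.
#' @param seed Integer seed.
#' @return Object of the same type with exactly `n` fragments.
#' @export
subsample_fragments <- function(fs, n, seed) {
  gr <- as_fragments(fs)
  if (n > length(gr)) {
    stop(sprintf("cannot subsample %d fragments from %d", n, length(gr)))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  keep <- sort(sample.int(length(gr), n))
  if (inherits(fs, "FragmentSet")) {
    fs$fragments <- gr[keep]
    fs
  } else {
    gr[keep]
  }
}

# Save/restore the global RNG state so seeded helpers do not perturb the
# caller's random stream.
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Derive a reproducible 31-bit sub-seed from a base seed and a string key,
# so each sample/stage gets its own stream and adding one never perturbs
# another. Plain integer arithmetic in doubles (exact below 2^53).
derive_seed <- function(seed, key) {
  h <- 0
  for (code in utf8ToInt(paste0(key))) {
    h <- (h * 131 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}
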