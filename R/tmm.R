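#' TMM normalization factors from a reads-in-peaks count matrix
#'
#' Trimmed mean of M-values computed on a regions x samples count matrix.
#' The reference sample is the one whose upper quartile of library-size-scaled
#' counts is closest to the mean upper quartile (ties broken by lowest column
#' index). For each sample, per-region log ratios
#' `M = log2((y_k/N_k)/(y_r/N_r))` and average abundances
#' `A = (log2(y_k/N_k) + log2(y_r/N_r))/2` are formed over regions with
#' finite values in both samples (zero-count regions drop out), the most
#' extreme M values (30% from each tail) and A values (5% from each tail)
#' are trimmed, and the factor is 2 to the inverse-variance-weighted mean of
#' the retained M, with weights from the binomial delta method. Factors are
#' rescaled so their geometric mean is 1.
#'
#' @param counts Numeric matrix, regions x samples (>= 2 columns, positive
#'   column sums).
#' @param logratio_trim,abundance_trim Per-tail trim fractions for M and A.
#' @return Numeric vector of per-sample factors (geometric mean 1).
#' @export
tmm_factors <- function(counts, logratio_trim = 0.3, abundance_trim = 0.05) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("TMM needs at least 2 samples")
  lib <- colSums(counts)
  if (any(lib <= 0)) stop("every sample must have a positive column sum")

  uq <- vapply(seq_len(ncol(counts)), function(j) {
    stats::quantile(counts[, j], 0.75) / lib[j]
  }, numeric(1))
  ref <- which.min(abs(uq - mean(uq)))

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair(counts[, j], counts[, ref], lib[j], lib[ref],
             logratio_trim, abundance_trim)
  }, numeric(1))
  f <- f / exp(mean(log(f)))
  names(f) <- colnames(counts)
  f
}

# One-sample-vs-reference trimmed mean of M-values.
tmm_pair <- function(obs, ref, n_obs, n_ref,
                     logratio_trim = 0.3, abundance_trim = 0.05) {
  p_obs <- obs / n_obs
  p_ref <- ref / n_ref
  logR <- log2(p_obs / p_ref)
  absE <- (log2(p_obs) + log2(p_ref)) / 2
  v <- (n_obs - obs) / (n_obs * obs) + (n_ref - ref) / (n_ref * ref)
  fin <- is.finite(logR) & is.finite(absE)
  logR <- logR[fin]; absE <- absE[fin]; v <- v[fin]
  if (length(logR) < 2) {
    warning("fewer than 2 usable regions for TMM; factor set to 1")
    return(1)
  }
  if (max(abs(logR)) < 1e-6) return(1)
  n <- length(logR)
  loL <- floor(n * logratio_trim) + 1
  hiL <- n + 1 - loL
  loS <- floor(n * abundance_trim) + 1
  hiS <- n + 1 - loS
  keep <- rank(logR) >= loL & rank(logR) <= hiL &
    rank(absE) >= loS & rank(absE) <= hiS
  if (!any(keep)) {
    warning("all regions trimmed in TMM; factor set to 1")
    return(1)
  }
  f <- sum(logR[keep] / v[keep]) / sum(1 / v[keep])
  if (!is.finite(f)) f <- 0
  2^f
}

#' Final per-million scale factor
#'
#' The spike-in-free scaling applied to each sample's raw track:
#' `1e6 / (tmm_factor x reads_in_peaks)`. Samples with more reads in peaks or
#' a larger composition factor are scaled down correspondingly.
#'
#' @param tmm_factor Positive TMM factor for the sample.
#' @param reads_in_peaks Positive total fragment count inside the peak set.
#' @return The multiplicative scale factor.
#' @examples
#' final_scale_factor(1.25, 800000)  # 1
#' @export
final_scale_factor <- function(tmm_factor, reads_in_peaks) {
  if (any(tmm_factor <= 0)) stop("tmm_factor must be > 0")
  if (any(reads_in_peaks <= 0)) stop("reads_in_peaks must be > 0")
  1e6 / (tmm_factor * reads_in_peaks)
}

#' Per-sample normalization summary
#'
#' Runs TMM on a reads-in-peaks matrix and tabulates, per sample, the TMM
#' factor, the reads-in-peaks count and the final scale factor.
#'
#' @param counts Count matrix, regions x samples.
#' @return data.frame with `sample_id`, `tmm_factor`, `reads_in_peaks`,
#'   `final_scale`.
#' @export
normalization_table <- function(counts) {
  f <- tmm_factors(counts)
  rip <- colSums(counts)
  data.frame(sample_id = colnames(counts) %||% as.character(seq_along(f)),
             tmm_factor = as.numeric(f),
             reads_in_peaks = as.numeric(rip),
             final_scale = final_scale_factor(as.numeric(f), as.numeric(rip)),
             stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
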