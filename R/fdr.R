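# Target-decoy FDR control on rule recall.
#
# Decoy rules are mined from a randomized library in which structure
# labels stay fixed while the peaks that generate features are shuffled
# across spectra; any decoy rule is therefore a chance association. The
# simple FDR at a recall threshold is the ratio of accepted decoy rules to
# accepted target rules, and rules are filtered at the smallest threshold
# achieving the requested FDR.

#' Build a decoy library by peak-pool permutation
#'
#' Keeps every record's structure label and peak count while replacing its
#' peaks with an equal-sized sample drawn without replacement from the
#' pooled peaks of all other records. This decouples spectral features
#' from structures (the null hypothesis of rule mining) while preserving
#' the mass distribution and per-spectrum feature load. Fragmentation-tree
#' edges are dropped: they refer to the original peaks. Deterministic
#' given the seed.
#'
#' @param lib A target [spectral_library()] with at least 2 records.
#' @param seed Integer seed.
#' @return A decoy [spectral_library()].
#' @export
make_decoy_library <- function(lib, seed) {
  stopifnot(inherits(lib, "ms2_library"), length(lib$records) >= 2L)
  n <- length(lib$records)
  sizes <- vapply(lib$records, function(r) nrow(r$peaks), integer(1L))
  pool <- do.call(rbind, lapply(lib$records, `[[`, "peaks"))
  owner <- rep(seq_len(n), sizes)
  records <- with_seed(seed, {
    lapply(seq_len(n), function(i) {
      rec <- lib$records[[i]]
      avail <- which(owner != i)
      take <- sample(avail, min(sizes[i], length(avail)))
      peaks <- pool[take, , drop = FALSE]
      # peak identity is 4-decimal mass: drop accidental duplicates, then
      # top up from the remaining pool to preserve the peak count
      peaks <- .dedupe_peaks(peaks)
      left <- setdiff(avail, take)
      while (nrow(peaks) < sizes[i] && length(left) > 0L) {
        extra <- sample(left, min(sizes[i] - nrow(peaks), length(left)))
        left <- setdiff(left, extra)
        peaks <- .dedupe_peaks(rbind(peaks, pool[extra, , drop = FALSE]))
      }
      spectrum_record(
        spectrum_id = rec$spectrum_id,
        peaks = peaks,
        precursor_mz = rec$precursor_mz,
        structure = rec$structure,
        inchikey_block1 = rec$inchikey_block1,
        tree_edges = NULL,
        metadata = rec$metadata
      )
    })
  })
  spectral_library(records, label = "decoy",
                   masses_are_neutral = lib$masses_are_neutral)
}

#' Simple FDR at a recall threshold
#'
#' The ratio of decoy to target rules with recall at or above the
#' threshold; 0 when both counts are 0, `Inf` when only decoys pass.
#'
#' @param target_recalls,decoy_recalls Numeric vectors of rule recalls.
#' @param t Threshold(s).
#' @return Numeric vector of FDR estimates, one per threshold.
#' @export
fdr_at_threshold <- function(target_recalls, decoy_recalls, t) {
  vapply(t, function(th) {
    g <- sum(target_recalls >= th)
    d <- sum(decoy_recalls >= th)
    if (g == 0L && d == 0L) 0 else d / g
  }, numeric(1L))
}

#' FDR as a function of the recall threshold
#'
#' @param target_recalls,decoy_recalls Numeric vectors of rule recalls.
#' @param thresholds Candidate thresholds; defaults to all observed
#'   recall values.
#' @param qvalue Also add a column with the cumulative-minimum (q-value)
#'   transform of the simple FDR.
#' @return Data frame (class `ms2_fdr_curve`) with columns `threshold`,
#'   `n_target`, `n_decoy`, `fdr` (and optionally `qvalue`), sorted by
#'   threshold.
#' @export
fdr_curve <- function(target_recalls, decoy_recalls, thresholds = NULL,
                      qvalue = FALSE) {
  thresholds <- sort(unique(thresholds %||% c(target_recalls, decoy_recalls)))
  df <- data.frame(
    threshold = thresholds,
    n_target = vapply(thresholds, function(t) sum(target_recalls >= t), integer(1L)),
    n_decoy = vapply(thresholds, function(t) sum(decoy_recalls >= t), integer(1L)),
    fdr = fdr_at_threshold(target_recalls, decoy_recalls, thresholds)
  )
  if (qvalue) df$qvalue <- rev(cummin(rev(df$fdr)))
  class(df) <- c("ms2_fdr_curve", "data.frame")
  df
}

#' Recall threshold achieving a target FDR
#'
#' The smallest observed target-recall value at which the simple FDR is at
#' most `alpha`.
#'
#' @param target_recalls,decoy_recalls Numeric vectors of rule recalls.
#' @param alpha FDR level.
#' @return A single threshold value.
#' @export
recall_threshold_for_fdr <- function(target_recalls, decoy_recalls,
                                     alpha = 0.01) {
  stopifnot(length(target_recalls) > 0L)
  cand <- sort(unique(target_recalls))
  fdr <- fdr_at_threshold(target_recalls, decoy_recalls, cand)
  ok <- which(fdr <= alpha)
  if (length(ok) == 0L) {
    stop("no recall threshold achieves FDR <= ", alpha,
         " (minimum attainable FDR: ", signif(min(fdr), 3),
         "); consider a larger alpha")
  }
  cand[min(ok)]
}

#' Filter target rules at a recall threshold
#'
#' Keeps exactly the target-origin rules with recall strictly above `t`
#' (a rule at the threshold is dropped), preserving order.
#'
#' @param rules An `ms2_rules` data frame.
#' @param t Recall threshold.
#' @return The filtered `ms2_rules` data frame.
#' @export
filter_rules <- function(rules, t) {
  out <- rules[rules$origin == "target" & rules$recall > t, , drop = FALSE]
  rownames(out) <- NULL
  out
}
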