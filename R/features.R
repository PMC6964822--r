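# Spectral features.
#
# A spectral feature is either a fragment's neutral exact mass ("Mass") or
# the difference between two masses ("MDiff"), always discretized by
# rounding to 4 decimal places. Feature sets are plain data frames with
# columns `ftype` and `value` (plus `spectrum_id` when tied to a
# spectrum), so they serialize directly as TSV.

.feature_frame <- function(ftype, value) {
  df <- unique(data.frame(
    ftype = as.character(ftype),
    value = round_mass(as.numeric(value)),
    stringsAsFactors = FALSE
  ))
  df <- df[df$value > 0, , drop = FALSE]
  df <- df[order(df$ftype, df$value), , drop = FALSE]
  rownames(df) <- NULL
  df
}

feature_key <- function(feats) {
  if (nrow(feats) == 0L) return(character(0L))  # paste0() would recycle ":"
  paste0(feats$ftype, ":", fmt_mass(feats$value))
}

#' All pairwise mass differences of a peak list
#'
#' One MDiff feature per unordered peak pair; for `n` distinct peaks with
#' distinct differences this yields `choose(n, 2)` features.
#'
#' @param peaks Numeric vector of masses in Da.
#' @return Feature data frame (`ftype`, `value`), all of type `"MDiff"`.
#' @export
all_mass_differences <- function(peaks) {
  peaks <- unique(round_mass(as.numeric(peaks)))
  if (length(peaks) < 2L) {
    return(.feature_frame(character(0L), numeric(0L)))
  }
  d <- abs(as.numeric(stats::dist(peaks)))
  .feature_frame(rep("MDiff", length(d)), d)
}

#' Extract target training features from a spectrum
#'
#' Target training uses only the fragmentation tree: Mass features are the
#' neutral masses of tree nodes, MDiff features are the parent - child
#' losses along tree edges. Using tree edges instead of all pairwise
#' differences keeps the feature space restricted to losses caused by
#' actual fragmentation reactions.
#'
#' @param rec An [spectrum_record()] with `tree_edges`.
#' @return Feature data frame with a `spectrum_id` column.
#' @export
extract_target_features <- function(rec) {
  stopifnot(inherits(rec, "ms2_spectrum"))
  if (is.null(rec$tree_edges) || nrow(rec$tree_edges) == 0L) {
    stop("record '", rec$spectrum_id, "' has no fragmentation-tree edges; ",
         "target training requires trees (use extract_query_features() ",
         "for tree-free spectra)")
  }
  nodes <- unique(round_mass(c(rec$tree_edges$parent_mass,
                               rec$tree_edges$child_mass)))
  losses <- rec$tree_edges$parent_mass - rec$tree_edges$child_mass
  out <- rbind(
    .feature_frame(rep("Mass", length(nodes)), nodes),
    .feature_frame(rep("MDiff", length(losses)), losses)
  )
  cbind(spectrum_id = rec$spectrum_id, out)
}

#' Extract decoy training features from a spectrum
#'
#' Draws a uniform random sample (without replacement) of
#' `floor(fraction * choose(n, 2))` MDiff features (at least one) from all
#' pairwise mass differences of the spectrum's peaks. The subsampling
#' introduces the randomness that makes decoy rules a null model while
#' keeping the decoy feature load comparable to the tree-edge features of
#' the target library.
#'
#' @param rec An [spectrum_record()].
#' @param fraction Fraction of all pairwise differences to keep.
#' @param seed Integer seed; the draw is deterministic given the seed.
#' @param include_masses Also emit the record's peak masses as Mass
#'   features (off by default: decoy feature sets are difference-only;
#'   the flag exists for sensitivity analysis).
#' @return Feature data frame with a `spectrum_id` column.
#' @export
extract_decoy_features <- function(rec, fraction = 0.2, seed,
                                   include_masses = FALSE) {
  stopifnot(inherits(rec, "ms2_spectrum"))
  md <- all_mass_differences(rec$peaks$mass)
  if (nrow(md) == 0L) {
    return(cbind(spectrum_id = character(0L), md))
  }
  n_keep <- max(1L, floor(fraction * nrow(md)))
  n_keep <- min(n_keep, nrow(md))
  idx <- with_seed(seed, sample.int(nrow(md), n_keep))
  out <- md[sort(idx), , drop = FALSE]
  if (include_masses) {
    out <- rbind(.feature_frame(rep("Mass", nrow(rec$peaks)), rec$peaks$mass),
                 out)
  }
  rownames(out) <- NULL
  cbind(spectrum_id = rec$spectrum_id, out)
}

#' Extract query features from a spectrum
#'
#' Mass features are the peak m/z values, neutralized by subtracting one
#' proton mass (1.00728 Da) under the positive-mode \[M+H\]+ assumption
#' unless `assume_protonated = FALSE`. MDiff features are all pairwise
#' differences among the peaks, plus precursor - peak differences when the
#' precursor m/z is known (losses from the precursor are the most
#' informative differences). The proton mass cancels in differences, so
#' MDiff features are adduct-independent.
#'
#' @param rec An [spectrum_record()] with at least one peak.
#' @param assume_protonated Subtract one proton from Mass features.
#' @return Feature data frame with a `spectrum_id` column.
#' @export
extract_query_features <- function(rec, assume_protonated = TRUE) {
  stopifnot(inherits(rec, "ms2_spectrum"))
  masses <- rec$peaks$mass
  neutral <- if (assume_protonated) masses - .PROTON_MASS else masses
  all_m <- masses
  if (!is.na(rec$precursor_mz)) all_m <- c(all_m, rec$precursor_mz)
  out <- rbind(
    .feature_frame(rep("Mass", length(neutral)), neutral),
    all_mass_differences(all_m)
  )
  cbind(spectrum_id = rec$spectrum_id, out)
}

#' Match two spectral features within a ppm tolerance
#'
#' Two features match when their types agree and their values differ by at
#' most `ppm` parts per million of the reference value.
#'
#' @param q_type,q_value Query feature type(s) and value(s).
#' @param r_type,r_value Reference feature type(s) and value(s).
#' @param ppm Relative mass tolerance in parts per million.
#' @return Logical vector.
#' @export
features_match <- function(q_type, q_value, r_type, r_value, ppm = 20) {
  q_type == r_type & abs(q_value - r_value) <= ppm * 1e-6 * r_value
}

#' Extract features for a whole library
#'
#' Applies the extractor matching the library label to every record:
#' tree-edge features for target libraries, subsampled mass differences
#' for decoy libraries, and full pairwise features for query libraries.
#'
#' @param lib An [spectral_library()] object.
#' @param decoy_fraction Fraction passed to [extract_decoy_features()].
#' @param seed Base seed for decoy subsampling (one derived seed per
#'   record); required for decoy libraries.
#' @param assume_protonated Passed to [extract_query_features()]; defaults
#'   to the library's `masses_are_neutral` flag being `FALSE`.
#' @return Feature data frame (`spectrum_id`, `ftype`, `value`).
#' @export
extract_features <- function(lib, decoy_fraction = 0.2, seed = NULL,
                             assume_protonated = NULL) {
  stopifnot(inherits(lib, "ms2_library"))
  out <- switch(
    lib$label,
    target = lapply(lib$records, extract_target_features),
    decoy = {
      if (is.null(seed)) stop("decoy feature extraction requires a seed")
      lapply(seq_along(lib$records), function(i) {
        extract_decoy_features(lib$records[[i]], fraction = decoy_fraction,
                               seed = seed + i)
      })
    },
    query = {
      prot <- assume_protonated %||% !lib$masses_are_neutral
      lapply(lib$records, extract_query_features, assume_protonated = prot)
    }
  )
  do.call(rbind, out)
}

#' Greedy ppm clustering of feature values
#'
#' Opt-in utility for libraries whose fragment masses are measured rather
#' than formula-derived: values within `ppm` of a cluster seed (processed
#' in ascending order, single linkage) are snapped to the seed so that
#' 4-decimal discretization groups them. Formula-annotated libraries do
#' not need this.
#'
#' @param values Numeric vector of feature values (one feature type).
#' @param ppm Clustering tolerance in ppm.
#' @return Numeric vector of snapped values, same length as `values`.
#' @export
cluster_feature_values <- function(values, ppm = 20) {
  ord <- order(values)
  v <- values[ord]
  out <- numeric(length(v))
  seed_val <- NA_real_
  for (i in seq_along(v)) {
    if (is.na(seed_val) || v[i] - seed_val > ppm * 1e-6 * seed_val) {
      seed_val <- v[i]
    }
    out[i] <- seed_val
  }
  out[order(ord)]
}
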