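# Workflow orchestration: train (library -> rule database), filter
# (target + decoy -> FDR-controlled database) and evaluate (rules on an
# independent test library), with a configuration object whose
# fingerprint is embedded in every output so incompatible artifacts are
# never combined.

#' Pipeline configuration
#'
#' Collects every tunable of the workflow in one object. The fingerprint
#' of the configuration is written into rule-database headers and checked
#' when databases are combined.
#'
#' @param rounding_decimals Mass discretization (decimal places).
#' @param ppm Query/motif matching tolerance in ppm.
#' @param min_supp_x,min_tp Mining thresholds (see [mine_rules()]).
#' @param max_body Maximum rule body size.
#' @param fdr_alpha FDR level for rule filtering.
#' @param sim_threshold Tanimoto threshold for analogous rules.
#' @param min_heavy_report Minimum heavy atoms of a reported
#'   recommendation.
#' @param max_cuts Bond-disconnection depth.
#' @param cleavage_policy Which bonds may be disconnected; acyclic single
#'   bonds between heavy atoms.
#' @param decoy_fraction Fraction of pairwise differences kept as decoy
#'   features.
#' @param fingerprint Fingerprint settings used for Tanimoto similarity.
#' @param aggregation Default aggregation mode.
#' @return A `ms2_config` list.
#' @export
pipeline_config <- function(rounding_decimals = 4L,
                            ppm = 20,
                            min_supp_x = 5L,
                            min_tp = 5L,
                            max_body = 3L,
                            fdr_alpha = 0.01,
                            sim_threshold = 0.5,
                            min_heavy_report = 5L,
                            max_cuts = 2L,
                            cleavage_policy = "all_acyclic",
                            decoy_fraction = 0.2,
                            fingerprint = "path1024x7",
                            aggregation = c("exhaustive", "fast", "naive")) {
  aggregation <- match.arg(aggregation)
  structure(
    list(rounding_decimals = rounding_decimals, ppm = ppm,
         min_supp_x = min_supp_x, min_tp = min_tp, max_body = max_body,
         fdr_alpha = fdr_alpha, sim_threshold = sim_threshold,
         min_heavy_report = min_heavy_report, max_cuts = max_cuts,
         cleavage_policy = cleavage_policy, decoy_fraction = decoy_fraction,
         fingerprint = fingerprint, aggregation = aggregation),
    class = "ms2_config"
  )
}

#' Configuration fingerprint string
#'
#' @param config A [pipeline_config()].
#' @return A single `key=value;...` string identifying the configuration.
#' @export
config_fingerprint <- function(config) {
  paste(names(config), unlist(config), sep = "=", collapse = ";")
}

#' Path to the shipped default substructure pattern list
#'
#' A small curated list of common functional groups and ring systems used
#' by the predefined-substructure route when the user supplies no pattern
#' file of their own.
#'
#' @return File path.
#' @export
default_pattern_file <- function() {
  system.file("extdata", "default_patterns.smi", package = "ms2rules",
              mustWork = TRUE)
}

#' Train: mine a rule database from a labeled library
#'
#' Merges spectra of identical structures (optional), extracts features
#' according to the library label, builds transactions and mines rules.
#'
#' @param lib A labeled [spectral_library()] (target or decoy).
#' @param patterns Character vector of predefined pattern SMILES.
#' @param config A [pipeline_config()].
#' @param merge Merge spectra sharing a structure first. Disable for
#'   libraries that are already one-spectrum-per-compound (e.g. simulated
#'   fixtures).
#' @param seed Seed for decoy feature subsampling (decoy libraries only).
#' @return List with `rules` (an `ms2_rules` data frame), `transactions`,
#'   and `report` (stage counts).
#' @export
run_train <- function(lib, patterns = read_pattern_file(default_pattern_file()),
                      config = pipeline_config(), merge = TRUE, seed = NULL) {
  stopifnot(inherits(lib, "ms2_library"))
  if (length(lib$records) == 0L) stop("empty library")
  n_in <- length(lib$records)
  if (merge) lib <- merge_by_structure(lib)
  feats <- extract_features(lib, decoy_fraction = config$decoy_fraction,
                            seed = seed)
  txns <- build_transactions(lib, feats, patterns,
                             max_cuts = config$max_cuts)
  rules <- mine_rules(txns, max_body = config$max_body,
                      min_supp_x = config$min_supp_x, min_tp = config$min_tp,
                      origin = if (lib$label == "decoy") "decoy" else "target")
  attr(rules, "config_fingerprint") <- config_fingerprint(config)
  list(
    rules = rules,
    transactions = txns,
    report = list(
      spectra_in = n_in,
      compounds = length(lib$records),
      transactions = length(txns),
      features = nrow(feats),
      substructures = length(attr(txns, "catalog")),
      rules = nrow(rules)
    )
  )
}

#' Filter: FDR-control a target rule database against a decoy database
#'
#' Chooses the smallest recall threshold achieving `alpha` simple FDR and
#' keeps target rules strictly above it. Refuses to combine rule sets
#' mined under different configurations.
#'
#' @param target_rules,decoy_rules `ms2_rules` data frames (with
#'   `config_fingerprint` attributes when produced by [run_train()] or
#'   [read_rule_db()]).
#' @param alpha FDR level.
#' @return List with `rules` (filtered), `threshold` and `curve` (an
#'   [fdr_curve()]).
#' @export
run_filter <- function(target_rules, decoy_rules, alpha = 0.01) {
  fp_t <- attr(target_rules, "config_fingerprint")
  fp_d <- attr(decoy_rules, "config_fingerprint")
  if (!is.null(fp_t) && !is.null(fp_d) && !is.na(fp_t) && !is.na(fp_d) &&
      !identical(fp_t, fp_d)) {
    stop("target and decoy rule databases were mined under different ",
         "configurations; refusing to combine them")
  }
  if (nrow(decoy_rules) == 0L) {
    threshold <- min(target_rules$recall)
  } else {
    threshold <- recall_threshold_for_fdr(target_rules$recall,
                                          decoy_rules$recall, alpha = alpha)
  }
  list(
    rules = filter_rules(target_rules, threshold),
    threshold = threshold,
    curve = fdr_curve(target_rules$recall, decoy_rules$recall)
  )
}

#' Evaluate: re-score rules on an independent test library
#'
#' Builds test transactions (tree-edge features when the test library has
#' trees, full pairwise features otherwise) and recomputes each rule's
#' confusion matrix.
#'
#' @param rules An `ms2_rules` data frame.
#' @param test_lib A structure-labeled [spectral_library()].
#' @param patterns Character vector of predefined pattern SMILES.
#' @param config A [pipeline_config()].
#' @param merge Merge test spectra sharing a structure first.
#' @return The [evaluate_rules()] data frame, with a `summary` attribute
#'   carrying the test recall distribution of evaluable rules.
#' @export
run_evaluate <- function(rules, test_lib,
                         patterns = read_pattern_file(default_pattern_file()),
                         config = pipeline_config(), merge = TRUE) {
  stopifnot(inherits(test_lib, "ms2_library"))
  labeled <- vapply(test_lib$records, function(r)
    !is.na(r$structure) || !is.na(r$inchikey_block1), logical(1L))
  if (!all(labeled)) stop("test library must be structure-labeled")
  if (merge) test_lib <- merge_by_structure(test_lib)
  has_trees <- all(vapply(test_lib$records, function(r)
    !is.null(r$tree_edges) && nrow(r$tree_edges) > 0L, logical(1L)))
  feats <- if (has_trees) {
    do.call(rbind, lapply(test_lib$records, extract_target_features))
  } else {
    do.call(rbind, lapply(test_lib$records, extract_query_features,
                          assume_protonated = !test_lib$masses_are_neutral))
  }
  txns <- build_transactions(test_lib, feats, patterns,
                             max_cuts = config$max_cuts)
  ev <- evaluate_rules(rules, txns, min_tp = config$min_tp)
  attr(ev, "summary") <- summary(ev$recall[ev$evaluable])
  ev
}

#' Annotate a query spectrum with substructure recommendations
#'
#' Extracts query features, matches the rule database and aggregates the
#' matched rules with the configured mode.
#'
#' @param rec A query [spectrum_record()].
#' @param rules An `ms2_rules` data frame (the filtered database).
#' @param config A [pipeline_config()].
#' @param mode Aggregation mode overriding the configuration.
#' @param assume_protonated Passed to [extract_query_features()].
#' @return List with `matches` (ranked matched rules) and
#'   `recommendations` (ranked aggregated substructures).
#' @export
annotate_spectrum <- function(rec, rules, config = pipeline_config(),
                              mode = config$aggregation,
                              assume_protonated = TRUE) {
  feats <- extract_query_features(rec, assume_protonated = assume_protonated)
  matches <- match_rules(feats, rules, ppm = config$ppm)
  recs <- switch(
    mode,
    naive = aggregate_naive(matches, min_heavy = config$min_heavy_report),
    fast = aggregate_fast(matches, sim_threshold = config$sim_threshold,
                          min_heavy = config$min_heavy_report),
    exhaustive = aggregate_exhaustive(matches,
                                      sim_threshold = config$sim_threshold,
                                      min_heavy = config$min_heavy_report)
  )
  list(matches = matches, recommendations = recs)
}
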