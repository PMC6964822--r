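#!/usr/bin/env Rscript
# Command-line front end for the ms2rules workflow.
#
#   Rscript scripts/ms2rules.R <command> [options]
#
# Commands:
#   simulate       --spec spec.json --out-dir DIR
#   train          --mgf lib.mgf --trees edges.tsv --patterns pat.smi
#                  --out rules.tsv [--kind target|decoy --seed N]
#   make-decoy     --mgf lib.mgf --seed N --out decoy.mgf
#   filter         --target rules.tsv --decoy decoy_rules.tsv
#                  --alpha 0.01 --out filtered.tsv --curve curve.tsv
#   evaluate       --rules rules.tsv --mgf test.mgf [--trees edges.tsv]
#                  --patterns pat.smi --out eval.tsv
#   annotate       --spectrum query.mgf --rules rules.tsv
#                  --mode exhaustive|fast|naive --ppm 20 --out recs.tsv
#   annotate-motif --motif motif.tsv --rules rules.tsv --top-k 50 --ppm 20
#
# Logging goes to stderr; result tables are written as TSV.

suppressMessages(library(ms2rules))

`%||%` <- function(a, b) if (is.null(a)) b else a

argv <- commandArgs(trailingOnly = TRUE)
if (length(argv) == 0L) stop("no command given; see header of this script")
cmd <- argv[1L]
argv <- argv[-1L]
opt <- function(flag, default = NULL) {
  i <- which(argv == flag)
  if (length(i) == 1L && i < length(argv)) argv[i + 1L] else default
}
need <- function(flag) {
  v <- opt(flag)
  if (is.null(v)) stop("missing required option ", flag)
  v
}
log_msg <- function(...) message("[ms2rules] ", ...)

read_lib <- function(path, kind, trees = NULL) {
  lib <- read_mgf(path, kind = kind)
  if (!is.null(trees)) lib <- attach_tree_edges(lib, read_tree_edges(trees))
  lib
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  log_msg("wrote ", path)
}

config <- pipeline_config(
  ppm = as.numeric(opt("--ppm", "20")),
  fdr_alpha = as.numeric(opt("--alpha", "0.01"))
)

if (cmd == "simulate") {
  spec_js <- jsonlite::read_json(need("--spec"), simplifyVector = TRUE)
  assoc <- lapply(seq_len(nrow(spec_js$associations)), function(i) {
    a <- spec_js$associations[i, ]
    planted_association(a$ftype, a$value, a$smiles, a$emit_prob,
                        a$leak_prob %||% 0)
  })
  pool <- spec_js$molecule_pool %||% default_molecule_pool()
  spec <- fixture_spec(spec_js$n_compounds, pool, assoc,
                       n_noise_features = spec_js$n_noise_features %||% 3L,
                       seed = as.integer(need("--seed")))
  out_dir <- opt("--out-dir", ".")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  lib <- generate_library(spec)
  write_mgf(lib, file.path(out_dir, "library.mgf"))
  edges <- do.call(rbind, lapply(lib$records, function(r)
    if (is.null(r$tree_edges)) NULL else
      cbind(spectrum_id = r$spectrum_id, r$tree_edges)))
  write_tsv(edges, file.path(out_dir, "tree_edges.tsv"))
  gt <- attr(lib, "ground_truth")
  jsonlite::write_json(
    list(associations = lapply(spec$associations, unclass),
         molecule = gt$molecule, root = gt$root),
    file.path(out_dir, "ground_truth.json"), auto_unbox = TRUE
  )
  log_msg("simulated ", length(lib$records), " spectra into ", out_dir)

} else if (cmd == "train") {
  kind <- opt("--kind", "target")
  lib <- read_lib(need("--mgf"), kind, opt("--trees"))
  pats <- if (is.null(opt("--patterns"))) {
    read_pattern_file(default_pattern_file())
  } else {
    read_pattern_file(opt("--patterns"))
  }
  seed <- opt("--seed")
  # --no-merge: the library is already one spectrum per compound
  # (e.g. produced by `simulate`)
  tr <- run_train(lib, patterns = pats, config = config,
                  merge = !("--no-merge" %in% argv),
                  seed = if (is.null(seed)) NULL else as.integer(seed))
  for (k in names(tr$report)) log_msg(k, ": ", tr$report[[k]])
  write_rule_db(tr$rules, need("--out"), config)
  log_msg("wrote ", need("--out"))

} else if (cmd == "make-decoy") {
  lib <- read_lib(need("--mgf"), "target")
  dec <- make_decoy_library(lib, seed = as.integer(need("--seed")))
  write_mgf(dec, need("--out"))
  log_msg("wrote ", need("--out"))

} else if (cmd == "filter") {
  tgt <- read_rule_db(need("--target"))
  dec <- read_rule_db(need("--decoy"))
  fl <- run_filter(tgt, dec, alpha = config$fdr_alpha)
  log_msg("recall threshold: ", fl$threshold,
          " (", nrow(fl$rules), "/", nrow(tgt), " target rules kept)")
  write_rule_db(fl$rules, need("--out"), config)
  curve_path <- opt("--curve")
  if (!is.null(curve_path)) write_tsv(as.data.frame(fl$curve), curve_path)

} else if (cmd == "evaluate") {
  rules <- read_rule_db(need("--rules"))
  lib <- read_lib(need("--mgf"), "target", opt("--trees"))
  pats <- if (is.null(opt("--patterns"))) {
    read_pattern_file(default_pattern_file())
  } else {
    read_pattern_file(opt("--patterns"))
  }
  ev <- run_evaluate(rules, lib, patterns = pats, config = config)
  write_tsv(ev, need("--out"))

} else if (cmd == "annotate") {
  rules <- read_rule_db(need("--rules"))
  lib <- read_mgf(need("--spectrum"), kind = "query")
  mode <- opt("--mode", "exhaustive")
  out <- need("--out")
  recs <- lapply(lib$records, function(rec) {
    ann <- annotate_spectrum(rec, rules, config = config, mode = mode)
    if (nrow(ann$recommendations) == 0L) return(NULL)
    cbind(spectrum_id = rec$spectrum_id, ann$recommendations)
  })
  recs <- do.call(rbind, Filter(Negate(is.null), recs))
  write_tsv(recs, out)

} else if (cmd == "annotate-motif") {
  rules <- read_rule_db(need("--rules"))
  motif <- utils::read.delim(need("--motif"), stringsAsFactors = FALSE)
  ann <- annotate_motif(motif, rules,
                        top_k = as.integer(opt("--top-k", "50")),
                        ppm = config$ppm)
  log_msg("status: ", ann$status)
  cat(ann$substructure, "\n")
  if (!is.null(ann$candidates)) {
    out <- opt("--out")
    if (!is.null(out)) write_tsv(ann$candidates, out)
  }

} else {
  stop("unknown command: ", cmd)
}
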