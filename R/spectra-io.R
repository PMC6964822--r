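# Spectral library input/output.
#
# Libraries are lists of spectrum records read from MGF files (BEGIN
# IONS/END IONS blocks). Besides the standard TITLE/PEPMASS/CHARGE keys,
# structure annotations travel in non-standard SMILES= and INCHIKEY= header
# keys; unrecognized keys are preserved as metadata. Fragmentation-tree
# edges (parent mass, child mass per spectrum) come from a companion TSV.

#' Construct a spectrum record
#'
#' @param spectrum_id Opaque identifier string.
#' @param peaks Data frame with columns `mass` (Da, > 0) and `intensity`
#'   (>= 0).
#' @param precursor_mz Precursor m/z in Da, or `NA`.
#' @param structure Structure annotation (SMILES) or `NA`.
#' @param inchikey_block1 First 14 characters of the InChIKey, or `NA`.
#' @param tree_edges Data frame with columns `parent_mass`, `child_mass`
#'   (each edge a neutral loss, parent > child), or `NULL`.
#' @param metadata Named character vector of extra MGF header keys.
#' @return An object of class `ms2_spectrum`.
#' @export
spectrum_record <- function(spectrum_id, peaks,
                            precursor_mz = NA_real_,
                            structure = NA_character_,
                            inchikey_block1 = NA_character_,
                            tree_edges = NULL,
                            metadata = character(0L)) {
  peaks <- as.data.frame(peaks)
  stopifnot(all(c("mass", "intensity") %in% names(peaks)))
  if (any(peaks$mass <= 0)) stop("all peak masses must be > 0")
  if (any(peaks$intensity < 0)) stop("peak intensities must be >= 0")
  if (anyDuplicated(round_mass(peaks$mass))) {
    peaks <- .dedupe_peaks(peaks)
  }
  if (!is.null(tree_edges)) {
    tree_edges <- as.data.frame(tree_edges)
    stopifnot(all(c("parent_mass", "child_mass") %in% names(tree_edges)))
    if (any(tree_edges$parent_mass <= tree_edges$child_mass)) {
      stop("tree edges must satisfy parent_mass > child_mass")
    }
    node <- round_mass(c(tree_edges$parent_mass, tree_edges$child_mass))
    if (!all(node %in% round_mass(peaks$mass))) {
      stop("tree node masses must be a subset of peak masses")
    }
  }
  structure(
    list(
      spectrum_id = as.character(spectrum_id),
      precursor_mz = as.numeric(precursor_mz),
      peaks = peaks[order(peaks$mass), , drop = FALSE],
      structure = structure,
      inchikey_block1 = inchikey_block1,
      tree_edges = tree_edges,
      metadata = metadata
    ),
    class = "ms2_spectrum"
  )
}

# Duplicate-fragment identity is mass equality after 4-decimal rounding;
# the most intense observation of each fragment is kept.
.dedupe_peaks <- function(peaks) {
  key <- fmt_mass(peaks$mass)
  peaks <- peaks[order(key, -peaks$intensity), , drop = FALSE]
  peaks <- peaks[!duplicated(fmt_mass(peaks$mass)), , drop = FALSE]
  rownames(peaks) <- NULL
  peaks[order(peaks$mass), , drop = FALSE]
}

#' @export
print.ms2_spectrum <- function(x, ...) {
  cat("<ms2_spectrum> ", x$spectrum_id, ": ", nrow(x$peaks), " peaks",
      if (!is.na(x$precursor_mz)) paste0(", precursor ", fmt_mass(x$precursor_mz)),
      if (!is.na(x$structure)) paste0(", structure ", x$structure),
      if (!is.null(x$tree_edges)) paste0(", ", nrow(x$tree_edges), " tree edges"),
      "\n", sep = "")
  invisible(x)
}

#' Construct a spectral library
#'
#' @param records List of [spectrum_record()] objects.
#' @param label Library role: `"target"`, `"decoy"` or `"query"`.
#' @param masses_are_neutral Whether peak masses are neutral exact masses
#'   (formula-annotated training data) rather than protonated m/z values.
#'   Defaults to neutral for target/decoy libraries and protonated for
#'   queries.
#' @return An object of class `ms2_library`.
#' @export
spectral_library <- function(records, label = c("target", "decoy", "query"),
                             masses_are_neutral = NULL) {
  label <- match.arg(label)
  stopifnot(all(vapply(records, inherits, logical(1L), "ms2_spectrum")))
  structure(
    list(
      records = records,
      label = label,
      masses_are_neutral = masses_are_neutral %||% (label != "query")
    ),
    class = "ms2_library"
  )
}

#' @export
print.ms2_library <- function(x, ...) {
  n_lab <- sum(vapply(x$records, function(r) !is.na(r$structure) ||
                        !is.na(r$inchikey_block1), logical(1L)))
  cat("<ms2_library> ", length(x$records), " ", x$label, " spectra (",
      n_lab, " structure-labeled, masses ",
      if (x$masses_are_neutral) "neutral" else "protonated", ")\n", sep = "")
  invisible(x)
}

#' @export
length.ms2_library <- function(x) length(x$records)

#' Read an MGF spectral library
#'
#' Parses BEGIN IONS/END IONS blocks. `SMILES=` and `INCHIKEY=` header keys
#' populate the structure fields; malformed peak lines are skipped with a
#' warning; blocks without any valid peak are rejected and counted in the
#' skip report (attribute `"skip_report"` of the result).
#'
#' @param path MGF file path.
#' @param kind Library role: `"target"`, `"decoy"` or `"query"`.
#' @return An [spectral_library()] object.
#' @export
read_mgf <- function(path, kind = c("target", "decoy", "query")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("cannot read MGF file: ", path)
  lines <- readLines(path, warn = FALSE)
  begins <- grep("^BEGIN IONS\\s*$", lines)
  ends <- grep("^END IONS\\s*$", lines)
  if (length(begins) == 0L || length(begins) != length(ends)) {
    stop("no complete BEGIN IONS/END IONS block in ", path)
  }
  records <- list()
  n_skipped_blocks <- 0L
  n_bad_peak_lines <- 0L
  for (bi in seq_along(begins)) {
    block <- lines[seq(begins[bi] + 1L, ends[bi] - 1L)]
    block <- block[nzchar(trimws(block))]
    is_kv <- grepl("=", block, fixed = TRUE)
    kv <- block[is_kv]
    keys <- toupper(sub("=.*$", "", kv))
    vals <- sub("^[^=]*=", "", kv)
    names(vals) <- keys

    peak_lines <- block[!is_kv]
    toks <- strsplit(trimws(peak_lines), "[[:space:]]+")
    mass <- suppressWarnings(vapply(toks, function(x) as.numeric(x[1L]), numeric(1L)))
    inten <- suppressWarnings(vapply(toks, function(x)
      if (length(x) >= 2L) as.numeric(x[2L]) else 1, numeric(1L)))
    bad <- is.na(mass) | mass <= 0
    n_bad_peak_lines <- n_bad_peak_lines + sum(bad)
    mass <- mass[!bad]
    inten <- ifelse(is.na(inten[!bad]), 1, inten[!bad])
    if (length(mass) == 0L) {
      n_skipped_blocks <- n_skipped_blocks + 1L
      next
    }
    get_kv <- function(key) if (key %in% names(vals)) vals[[key]] else NA_character_
    prec <- suppressWarnings(as.numeric(strsplit(
      get_kv("PEPMASS"), "[[:space:]]+")[[1L]][1L]))
    ik <- get_kv("INCHIKEY")
    title <- get_kv("TITLE")
    if (is.na(title)) title <- get_kv("SCANS")
    known <- c("TITLE", "PEPMASS", "CHARGE", "SMILES", "INCHIKEY")
    records[[length(records) + 1L]] <- spectrum_record(
      spectrum_id = if (is.na(title)) sprintf("spectrum_%04d", bi) else title,
      peaks = data.frame(mass = mass, intensity = inten),
      precursor_mz = prec,
      structure = get_kv("SMILES"),
      inchikey_block1 = if (is.na(ik)) NA_character_ else substr(ik, 1L, 14L),
      metadata = vals[setdiff(names(vals), known)]
    )
  }
  if (n_bad_peak_lines > 0L) {
    warning(n_bad_peak_lines, " malformed peak line(s) skipped in ", path,
            call. = FALSE)
  }
  lib <- spectral_library(records, label = kind)
  attr(lib, "skip_report") <- list(
    blocks_total = length(begins),
    blocks_skipped = n_skipped_blocks,
    bad_peak_lines = n_bad_peak_lines
  )
  lib
}

#' Write a spectral library to MGF
#'
#' Masses are written with 4 decimals (the package-wide discretization).
#'
#' @param lib An [spectral_library()] object.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(lib, path) {
  stopifnot(inherits(lib, "ms2_library"))
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in lib$records) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", rec$spectrum_id), con)
    if (!is.na(rec$precursor_mz)) {
      writeLines(paste0("PEPMASS=", fmt_mass(rec$precursor_mz)), con)
    }
    if (!is.na(rec$structure)) writeLines(paste0("SMILES=", rec$structure), con)
    if (!is.na(rec$inchikey_block1)) {
      writeLines(paste0("INCHIKEY=", rec$inchikey_block1), con)
    }
    if (length(rec$metadata) > 0L) {
      writeLines(paste0(names(rec$metadata), "=", rec$metadata), con)
    }
    writeLines(sprintf("%s %g", fmt_mass(rec$peaks$mass), rec$peaks$intensity), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}

# Structure identity for merging/deduplication: InChIKey first block when
# available, else the canonical SMILES.
.structure_key <- function(rec) {
  if (!is.na(rec$inchikey_block1)) return(rec$inchikey_block1)
  if (!is.na(rec$structure)) {
    can <- canonical_smiles(rec$structure)
    if (!is.na(can)) return(can)
  }
  NA_character_
}

#' Merge spectra of identical structures
#'
#' Records sharing a structure identity (InChIKey first block, falling
#' back to canonical SMILES) are combined into a single record: peak sets
#' are unioned with duplicate fragments (equal after 4-decimal rounding)
#' kept once, and tree edges are unioned. Records without any structure
#' label are left unmerged with a warning. Merging is idempotent.
#'
#' @param lib An [spectral_library()] object.
#' @return A merged [spectral_library()] with at most one record per
#'   structure identity.
#' @export
merge_by_structure <- function(lib) {
  stopifnot(inherits(lib, "ms2_library"))
  keys <- vapply(lib$records, .structure_key, character(1L))
  if (anyNA(keys)) {
    warning(sum(is.na(keys)), " record(s) without structure label left unmerged",
            call. = FALSE)
  }
  groups <- split(seq_along(keys), keys, drop = TRUE)
  singles <- which(is.na(keys))
  merged <- lapply(groups, function(idx) .merge_records(lib$records[idx]))
  out <- c(merged, lib$records[singles])
  # keep original library ordering by first member
  first_idx <- c(vapply(groups, min, integer(1L)), singles)
  out <- out[order(first_idx)]
  spectral_library(unname(out), label = lib$label,
                   masses_are_neutral = lib$masses_are_neutral)
}

.merge_records <- function(recs) {
  if (length(recs) == 1L) return(recs[[1L]])
  peaks <- do.call(rbind, lapply(recs, `[[`, "peaks"))
  peaks <- .dedupe_peaks(peaks)
  edges <- do.call(rbind, Filter(Negate(is.null), lapply(recs, `[[`, "tree_edges")))
  if (!is.null(edges) && nrow(edges) > 0L) {
    ekey <- paste(fmt_mass(edges$parent_mass), fmt_mass(edges$child_mass))
    edges <- edges[!duplicated(ekey), , drop = FALSE]
    rownames(edges) <- NULL
  }
  base <- recs[[1L]]
  spectrum_record(
    spectrum_id = base$spectrum_id,
    peaks = peaks,
    precursor_mz = base$precursor_mz,
    structure = base$structure,
    inchikey_block1 = base$inchikey_block1,
    tree_edges = edges,
    metadata = base$metadata
  )
}

#' Read fragmentation-tree edges
#'
#' Reads a TSV with columns `spectrum_id`, `parent_mass`, `child_mass`.
#' Rows with `parent_mass <= child_mass` are rejected with a warning.
#'
#' @param path TSV file path.
#' @return Named list mapping spectrum id to an edge data frame.
#' @export
read_tree_edges <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) return(list())
  stopifnot(all(c("spectrum_id", "parent_mass", "child_mass") %in% names(df)))
  bad <- df$parent_mass <= df$child_mass
  if (any(bad)) {
    warning(sum(bad), " edge row(s) rejected (parent_mass <= child_mass)",
            call. = FALSE)
    df <- df[!bad, , drop = FALSE]
  }
  split(df[c("parent_mass", "child_mass")], df$spectrum_id)
}

#' Attach fragmentation-tree edges to library records
#'
#' Edges referencing masses absent from the record's peak list (after
#' 4-decimal rounding) are rejected with a warning.
#'
#' @param lib An [spectral_library()] object.
#' @param edge_map Named list from [read_tree_edges()].
#' @return The library with `tree_edges` populated.
#' @export
attach_tree_edges <- function(lib, edge_map) {
  stopifnot(inherits(lib, "ms2_library"))
  n_rejected <- 0L
  lib$records <- lapply(lib$records, function(rec) {
    ed <- edge_map[[rec$spectrum_id]]
    if (is.null(ed) || nrow(ed) == 0L) return(rec)
    pk <- round_mass(rec$peaks$mass)
    ok <- round_mass(ed$parent_mass) %in% pk & round_mass(ed$child_mass) %in% pk
    n_rejected <<- n_rejected + sum(!ok)
    ed <- ed[ok, , drop = FALSE]
    if (nrow(ed) > 0L) rec$tree_edges <- ed
    rec
  })
  if (n_rejected > 0L) {
    warning(n_rejected, " edge(s) referencing unknown peak masses rejected",
            call. = FALSE)
  }
  lib
}
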