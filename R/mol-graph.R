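# Molecular graphs.
#
# Structures enter the package as SMILES strings. Open Babel (through
# ChemmineOB::convertFormat) handles SMILES parsing, aromaticity perception
# and canonicalization; the TRIPOS MOL2 text it emits is turned into an
# atom table, a bond table and an igraph graph on which all subgraph work
# (containment, cleavage, maximum common substructure) is done. Parsed
# molecules are cached per session because libraries reuse a small pool of
# structures many times.

.mol_cache <- new.env(parent = emptyenv())

# Bond orders are kept as MOL2 order codes and mapped to integer colors
# for matching: single/amide = 1, double = 2, triple = 3, aromatic = 4.
.bond_color <- function(order) {
  unname(c("1" = 1L, "2" = 2L, "3" = 3L, "am" = 1L, "ar" = 4L,
           "du" = 1L, "un" = 1L, "nc" = 0L)[order])
}

#' Canonicalize SMILES strings
#'
#' Converts SMILES to Open Babel canonical SMILES. Canonicalization is a
#' fixed point: applying it twice gives the same string.
#'
#' @param smiles Character vector of SMILES strings.
#' @return Character vector of canonical SMILES; `NA` where a string does
#'   not parse.
#' @export
canonical_smiles <- function(smiles) {
  vapply(as.character(smiles), function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    key <- paste0("can\r", s)
    hit <- .mol_cache[[key]]
    if (!is.null(hit)) return(hit)
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", s),
      error = function(e) ""
    )
    out <- sub("[\t ].*$", "", sub("\n$", "", out))
    out <- if (nzchar(out)) out else NA_character_
    assign(key, out, envir = .mol_cache)
    out
  }, character(1L), USE.NAMES = FALSE)
}

# Parse one TRIPOS MOL2 text into atom/bond tables. Hydrogens are dropped
# (they stay implicit everywhere in the package); atom indices are
# renumbered over heavy atoms.
.parse_mol2 <- function(txt) {
  lines <- strsplit(txt, "\n", fixed = TRUE)[[1L]]
  a0 <- grep("^@<TRIPOS>ATOM", lines)
  b0 <- grep("^@<TRIPOS>BOND", lines)
  if (length(a0) != 1L || length(b0) != 1L) return(NULL)
  sec_end <- function(start) {
    nxt <- grep("^@<TRIPOS>", lines)
    nxt <- nxt[nxt > start]
    if (length(nxt) == 0L) length(lines) else min(nxt) - 1L
  }
  atom_lines <- lines[seq(a0 + 1L, sec_end(a0))]
  atom_lines <- atom_lines[nzchar(trimws(atom_lines))]
  bond_lines <- if (sec_end(b0) >= b0 + 1L) lines[seq(b0 + 1L, sec_end(b0))] else character(0L)
  bond_lines <- bond_lines[nzchar(trimws(bond_lines))]

  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  sybyl <- vapply(af, `[`, character(1L), 6L)
  elem <- sub("\\..*$", "", sybyl)
  charge <- vapply(af, function(x) if (length(x) >= 9L) x[9L] else "0.0", character(1L))

  heavy <- elem != "H"
  idx_map <- integer(length(elem))
  idx_map[heavy] <- seq_len(sum(heavy))

  bonds <- NULL
  if (length(bond_lines) > 0L) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    b1 <- vapply(bf, function(x) as.integer(x[2L]), integer(1L))
    b2 <- vapply(bf, function(x) as.integer(x[3L]), integer(1L))
    bo <- vapply(bf, `[`, character(1L), 4L)
    keep <- heavy[b1] & heavy[b2]
    bonds <- data.frame(
      a = idx_map[b1[keep]], b = idx_map[b2[keep]],
      order = bo[keep], stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(a = integer(0L), b = integer(0L),
                        order = character(0L), stringsAsFactors = FALSE)
  }
  list(
    atoms = data.frame(elem = elem[heavy], sybyl = sybyl[heavy],
                       charge = charge[heavy], stringsAsFactors = FALSE),
    bonds = bonds
  )
}

# Build the igraph representation: vertices carry the element, edges carry
# the MOL2 bond order code and its integer color.
.mol_graph <- function(atoms, bonds) {
  g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
  igraph::V(g)$elem <- atoms$elem
  if (nrow(bonds) > 0L) {
    g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
    igraph::E(g)$order <- bonds$order
    igraph::E(g)$ocolor <- .bond_color(bonds$order)
  }
  g
}

#' Parse a structure into a molecular graph
#'
#' @param smiles A single SMILES string.
#' @return An object of class `ms2_mol`: a list with elements `smiles`
#'   (canonical form), `atoms`, `bonds` and `graph` (heavy atoms only,
#'   hydrogens implicit), or an error if the string does not parse.
#' @export
parse_mol <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  key <- paste0("mol\r", smiles)
  hit <- .mol_cache[[key]]
  if (!is.null(hit)) return(hit)
  txt <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", smiles),
    error = function(e) ""
  )
  parsed <- if (nzchar(txt)) .parse_mol2(txt) else NULL
  if (is.null(parsed) || nrow(parsed$atoms) == 0L) {
    stop("structure does not parse as SMILES: '", smiles, "'")
  }
  mol <- structure(
    list(
      smiles = canonical_smiles(smiles),
      atoms = parsed$atoms,
      bonds = parsed$bonds,
      graph = .mol_graph(parsed$atoms, parsed$bonds)
    ),
    class = "ms2_mol"
  )
  assign(key, mol, envir = .mol_cache)
  mol
}

#' @export
print.ms2_mol <- function(x, ...) {
  cat("<ms2_mol> ", x$smiles, " (", nrow(x$atoms), " heavy atoms, ",
      nrow(x$bonds), " bonds)\n", sep = "")
  invisible(x)
}

# Serialize an atom/bond selection of a molecule back to MOL2 so Open
# Babel can canonicalize the fragment. Aromatic bonds that end up outside
# any ring of the fragment (bridges) are demoted to single bonds: aromatic
# character is undefined for acyclic fragments and Open Babel would emit
# unreadable SMILES for them. Open valences at cut sites are filled with
# implicit hydrogens by construction.
.write_mol2 <- function(atoms, bonds) {
  demote <- rep(FALSE, nrow(bonds))
  if (nrow(bonds) > 0L) {
    g <- igraph::make_empty_graph(n = nrow(atoms), directed = FALSE)
    g <- igraph::add_edges(g, rbind(bonds$a, bonds$b))
    br <- igraph::bridges(g)
    demote <- seq_len(nrow(bonds)) %in% as.integer(br) & bonds$order == "ar"
  }
  order_out <- ifelse(demote, "1", bonds$order)
  sybyl_out <- atoms$sybyl
  # atoms that lost all aromatic bonds get their plain element type
  if (any(demote)) {
    still_ar <- unique(c(bonds$a[order_out == "ar"], bonds$b[order_out == "ar"]))
    lost <- setdiff(unique(c(bonds$a[demote], bonds$b[demote])), still_ar)
    sybyl_out[lost] <- ifelse(
      atoms$elem[lost] %in% c("C", "N", "O", "S", "P"),
      paste0(atoms$elem[lost], ".3"), atoms$elem[lost]
    )
  }
  paste0(
    "@<TRIPOS>MOLECULE\n*\n ", nrow(atoms), " ", nrow(bonds),
    " 0 0 0\nSMALL\nNO_CHARGES\n\n@<TRIPOS>ATOM\n",
    paste(sprintf("%7d %-4s 0.0 0.0 0.0 %-6s 1 UNL1 %s",
                  seq_len(nrow(atoms)), atoms$elem, sybyl_out, atoms$charge),
          collapse = "\n"),
    "\n@<TRIPOS>BOND\n",
    if (nrow(bonds) > 0L) {
      paste(sprintf("%6d %5d %5d %s", seq_len(nrow(bonds)),
                    bonds$a, bonds$b, order_out),
            collapse = "\n")
    } else "",
    "\n"
  )
}

# Canonical SMILES of the fragment induced by vertex ids `vids` of `mol`,
# optionally restricted to the bonds in `bond_rows` (row indices into
# mol$bonds). NA when Open Babel cannot serialize the fragment.
.fragment_smiles <- function(mol, vids, bond_rows = NULL) {
  vids <- sort(unique(as.integer(vids)))
  rows <- if (is.null(bond_rows)) {
    which(mol$bonds$a %in% vids & mol$bonds$b %in% vids)
  } else {
    bond_rows
  }
  remap <- integer(nrow(mol$atoms))
  remap[vids] <- seq_along(vids)
  atoms <- mol$atoms[vids, , drop = FALSE]
  bonds <- mol$bonds[rows, , drop = FALSE]
  bonds$a <- remap[bonds$a]
  bonds$b <- remap[bonds$b]
  txt <- .write_mol2(atoms, bonds)
  out <- tryCatch(
    ChemmineOB::convertFormat("MOL2", "CAN", txt),
    error = function(e) ""
  )
  out <- sub("[\t ].*$", "", sub("\n$", "", out))
  if (nzchar(out)) out else NA_character_
}
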