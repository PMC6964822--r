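# Substructure objects and the subgraph machinery behind them:
# containment testing, substructure generation from a molecule (predefined
# pattern list and bond cleavage), the triviality filter, path-fingerprint
# Tanimoto similarity, and maximum common substructure extraction.

#' Construct a substructure
#'
#' A substructure is a connected molecular fragment represented by its
#' canonical SMILES together with element counts used by the triviality
#' filter and the recommendation size filter.
#'
#' @param smiles SMILES string of the fragment.
#' @param source Provenance: `"predefined"` (pattern list) or
#'   `"cleavage"` (bond disconnection).
#' @return An object of class `ms2_substructure` with fields `smiles`
#'   (canonical), `n_carbon`, `n_oxygen`, `n_heavy`, `elements`, `source`.
#' @export
substructure <- function(smiles, source = c("predefined", "cleavage")) {
  source <- match.arg(source)
  mol <- parse_mol(smiles)
  elems <- mol$atoms$elem
  structure(
    list(
      smiles = mol$smiles,
      n_carbon = sum(elems == "C"),
      n_oxygen = sum(elems == "O"),
      n_heavy = length(elems),
      elements = sort(unique(elems)),
      source = source
    ),
    class = "ms2_substructure"
  )
}

#' @export
print.ms2_substructure <- function(x, ...) {
  cat("<ms2_substructure> ", x$smiles, " [", x$source, ", ", x$n_heavy,
      " heavy atoms]\n", sep = "")
  invisible(x)
}

.as_mol <- function(x) {
  if (inherits(x, "ms2_mol")) return(x)
  if (inherits(x, "ms2_substructure")) return(parse_mol(x$smiles))
  parse_mol(as.character(x))
}

#' Triviality filter for substructures
#'
#' A fragment is trivial when it is built only from C, H, O and N and its
#' combined carbon + oxygen count is below five. Trivial fragments (short
#' aliphatic stubs, water-sized pieces) carry essentially no structural
#' information and are discarded during substructure generation. Fragments
#' containing any other element (halogens, S, P, ...) are never trivial.
#'
#' @param sub An `ms2_substructure`.
#' @return `TRUE` if the fragment is trivial.
#' @export
is_trivial <- function(sub) {
  stopifnot(inherits(sub, "ms2_substructure"))
  chon <- all(sub$elements %in% c("C", "H", "O", "N"))
  chon && (sub$n_carbon + sub$n_oxygen) < 5L
}

# Shared integer-coloring of two graphs' vertices by element so VF2 can
# match on them.
.color_pair <- function(g1, g2) {
  univ <- union(igraph::V(g1)$elem, igraph::V(g2)$elem)
  list(
    c1 = match(igraph::V(g1)$elem, univ),
    c2 = match(igraph::V(g2)$elem, univ)
  )
}

.ecolor <- function(g) {
  if (igraph::ecount(g) == 0L) integer(0L) else igraph::E(g)$ocolor
}

#' Test substructure containment
#'
#' Decides whether `sub` embeds in `mol` as a subgraph with matching
#' elements and bond orders (aromatic bonds match only aromatic bonds);
#' hydrogen counts are ignored. This is a monomorphism test: ring atoms of
#' `mol` may carry extra bonds not present in `sub`.
#'
#' @param mol Molecule: SMILES string, `ms2_mol`, or `ms2_substructure`.
#' @param sub Substructure to look for, same accepted types.
#' @return `TRUE` if `sub` is contained in `mol`.
#' @export
contains_substructure <- function(mol, sub) {
  m <- .as_mol(mol)
  s <- .as_mol(sub)
  if (nrow(s$atoms) > nrow(m$atoms)) return(FALSE)
  cols <- .color_pair(m$graph, s$graph)
  # color1/edge.color1 refer to the target graph, color2 to the pattern
  igraph::subgraph_isomorphic(
    s$graph, m$graph, method = "vf2",
    vertex.color1 = cols$c1, vertex.color2 = cols$c2,
    edge.color1 = .ecolor(m$graph), edge.color2 = .ecolor(s$graph)
  )
}

#' Read a substructure pattern list
#'
#' One SMILES per line; blank lines and `#` comments are ignored.
#' Unparsable lines are skipped with a warning.
#'
#' @param path Path to the pattern file.
#' @return Character vector of pattern SMILES.
#' @export
read_pattern_file <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Match predefined substructure patterns against a molecule
#'
#' Returns the subset of `patterns` embedded in `mol`, as canonical
#' substructures with `source = "predefined"`. Patterns that fail to parse
#' are skipped with a warning. The predefined route complements bond
#' cleavage: it contributes ring systems and functional groups that no
#' acyclic disconnection can produce.
#'
#' @param mol Molecule (SMILES string or `ms2_mol`).
#' @param patterns Character vector of pattern SMILES.
#' @return List of `ms2_substructure` objects (possibly empty).
#' @export
predefined_substructures <- function(mol, patterns) {
  m <- .as_mol(mol)
  out <- list()
  for (p in patterns) {
    sub <- tryCatch(substructure(p, source = "predefined"), error = function(e) NULL)
    if (is.null(sub)) {
      warning("skipping unparsable pattern: '", p, "'", call. = FALSE)
      next
    }
    if (sub$n_heavy < 2L) next  # single atoms are uninformative
    if (contains_substructure(m, sub)) out[[sub$smiles]] <- sub
  }
  unname(out)
}

#' Generate substructures by bond disconnection
#'
#' Disconnects one or (for `max_cuts = 2`) two acyclic single bonds
#' between heavy atoms and collects the resulting two or three fragments.
#' Cutting is restricted to acyclic (bridge) single bonds so that every
#' cut separates the molecule; ring bonds and multiple bonds are never
#' cut. Fragments are canonicalized, and fragments that are trivial (see
#' [is_trivial()]) or smaller than `min_heavy` heavy atoms are discarded.
#'
#' @param mol Molecule (SMILES string or `ms2_mol`).
#' @param max_cuts 1 or 2 simultaneous bond disconnections.
#' @param min_heavy Minimum fragment size in heavy atoms (default 2).
#' @return List of unique `ms2_substructure` objects with
#'   `source = "cleavage"`.
#' @export
cleavage_substructures <- function(mol, max_cuts = 2L, min_heavy = 2L) {
  stopifnot(max_cuts %in% c(1L, 2L))
  m <- .as_mol(mol)
  g <- m$graph
  if (igraph::ecount(g) == 0L) return(list())
  bridge_ids <- as.integer(igraph::bridges(g))
  cuttable <- bridge_ids[m$bonds$order[bridge_ids] %in% c("1", "am")]
  if (length(cuttable) == 0L) return(list())

  cut_sets <- lapply(cuttable, function(i) i)
  if (max_cuts == 2L && length(cuttable) >= 2L) {
    pairs <- utils::combn(cuttable, 2L, simplify = FALSE)
    cut_sets <- c(cut_sets, pairs)
  }

  seen <- new.env(parent = emptyenv())
  out <- list()
  for (cs in cut_sets) {
    g2 <- igraph::delete_edges(g, cs)
    comp <- igraph::components(g2)
    # two bridges always yield 3 components, one bridge yields 2
    for (k in seq_len(comp$no)) {
      vids <- which(comp$membership == k)
      if (length(vids) < min_heavy) next
      smi <- .fragment_smiles(m, vids)
      if (is.na(smi) || !is.null(seen[[smi]])) next
      assign(smi, TRUE, envir = seen)
      sub <- tryCatch(substructure(smi, source = "cleavage"), error = function(e) NULL)
      if (is.null(sub) || sub$n_heavy < min_heavy || is_trivial(sub)) next
      out[[length(out) + 1L]] <- sub
    }
  }
  out
}

# --- path fingerprint ------------------------------------------------------

# Linear-path hashed fingerprint: all simple paths of 1..max_len bonds are
# encoded as element/bond-order strings (canonical direction = lexicographic
# minimum of the two readings) and hashed onto `nbits` bits.
.hash_string <- function(s, nbits) {
  codes <- utf8ToInt(s)
  h <- 0
  for (cc in codes) h <- (h * 31 + cc) %% 1048573
  as.integer(h %% nbits) + 1L
}

.path_bits <- function(mol, nbits = 1024L, max_len = 7L) {
  g <- mol$graph
  n <- igraph::vcount(g)
  if (n == 0L) return(integer(0L))
  elem <- igraph::V(g)$elem
  adj <- igraph::as_adj_list(g)
  ends <- igraph::ends(g, igraph::E(g), names = FALSE)
  ord <- if (igraph::ecount(g) > 0L) igraph::E(g)$order else character(0L)
  bond_of <- new.env(parent = emptyenv())
  if (igraph::ecount(g) > 0L) {
    for (i in seq_len(nrow(ends))) {
      assign(paste(ends[i, 1L], ends[i, 2L]), ord[i], envir = bond_of)
      assign(paste(ends[i, 2L], ends[i, 1L]), ord[i], envir = bond_of)
    }
  }
  paths <- character(0L)
  walk <- function(path, fwd, rev) {
    last <- path[length(path)]
    for (nb in adj[[last]]) {
      if (nb %in% path) next
      bo <- get(paste(last, nb), envir = bond_of)
      f2 <- paste0(fwd, bo, elem[nb])
      r2 <- paste0(elem[nb], bo, rev)
      paths[[length(paths) + 1L]] <<- if (f2 <= r2) f2 else r2
      if (length(path) < max_len) walk(c(path, nb), f2, r2)
    }
  }
  for (v in seq_len(n)) walk(v, elem[v], elem[v])
  unique(vapply(unique(paths), .hash_string, integer(1L), nbits = nbits))
}

#' Tanimoto similarity of two substructures
#'
#' Jaccard coefficient of hashed linear-path fingerprints (1024 bits,
#' paths up to 7 bonds, element- and bond-order-labelled). Identical
#' structures score 1; structures sharing no path bit score 0.
#'
#' @param a,b Substructures (SMILES strings or `ms2_substructure`).
#' @param nbits Fingerprint width in bits.
#' @param max_len Maximum path length in bonds.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b, nbits = 1024L, max_len = 7L) {
  ma <- .as_mol(a)
  mb <- .as_mol(b)
  fa <- .fingerprint_cached(ma, nbits, max_len)
  fb <- .fingerprint_cached(mb, nbits, max_len)
  if (length(fa) == 0L && length(fb) == 0L) {
    return(if (identical(ma$smiles, mb$smiles)) 1 else 0)
  }
  length(intersect(fa, fb)) / length(union(fa, fb))
}

.fingerprint_cached <- function(mol, nbits, max_len) {
  key <- paste0("fp\r", nbits, "\r", max_len, "\r", mol$smiles)
  hit <- .mol_cache[[key]]
  if (!is.null(hit)) return(hit)
  fp <- .path_bits(mol, nbits, max_len)
  assign(key, fp, envir = .mol_cache)
  fp
}

# --- maximum common substructure -------------------------------------------

#' Maximum common substructure of two fragments
#'
#' Finds a largest connected common subgraph of `a` and `b` with matching
#' elements and bond orders (charge and stereochemistry ignored), via
#' maximal-clique search on the modular product of the two molecular
#' graphs. Among equally large solutions the one with the
#' lexicographically smallest canonical SMILES is returned, so the result
#' is deterministic.
#'
#' @param a,b Fragments (SMILES strings or `ms2_substructure`).
#' @param min_heavy Minimum size of a reportable MCS in heavy atoms.
#' @param time_budget Per-pair CPU budget in seconds; when exceeded the
#'   function returns `NULL` with a warning.
#' @return An `ms2_substructure` (with `source = "cleavage"`), or `NULL`
#'   when no common subgraph of `min_heavy` atoms exists or the budget is
#'   exhausted.
#' @export
mcs <- function(a, b, min_heavy = 2L, time_budget = 1) {
  ma <- .as_mol(a)
  mb <- .as_mol(b)
  key <- paste0("mcs\r", min_heavy, "\r",
                paste(sort(c(ma$smiles, mb$smiles)), collapse = "\r"))
  hit <- .mol_cache[[key]]
  if (!is.null(hit)) return(if (identical(hit, "none")) NULL else hit)

  res <- tryCatch(
    .mcs_core(ma, mb, min_heavy, deadline = Sys.time() + time_budget),
    ms2rules_mcs_timeout = function(c) {
      warning("MCS time budget (", time_budget, " s) exceeded for pair ",
              ma$smiles, " / ", mb$smiles, "; pair skipped", call. = FALSE)
      NULL
    }
  )
  assign(key, if (is.null(res)) "none" else res, envir = .mol_cache)
  res
}

# Bond-order adjacency matrix, 0 = no bond.
.adj_orders <- function(mol) {
  n <- nrow(mol$atoms)
  m <- matrix(0L, n, n)
  if (nrow(mol$bonds) > 0L) {
    idx <- cbind(mol$bonds$a, mol$bonds$b)
    col <- .bond_color(mol$bonds$order)
    m[idx] <- col
    m[idx[, 2:1, drop = FALSE]] <- col
  }
  m
}

# Exact connected maximum common induced subgraph by depth-first extension
# of partial atom mappings. Pure R so the time budget can interrupt it;
# visited mapping-sets are memoized to collapse the permutation blow-up.
.mcs_core <- function(ma, mb, min_heavy, deadline) {
  na_ <- nrow(ma$atoms)
  nb_ <- nrow(mb$atoms)
  ea <- ma$atoms$elem
  eb <- mb$atoms$elem
  if (!any(ea %in% eb)) return(NULL)
  Aa <- .adj_orders(ma)
  Ab <- .adj_orders(mb)

  best <- new.env(parent = emptyenv())
  best$size <- min_heavy - 1L
  best$smi <- NULL
  seen <- new.env(parent = emptyenv())
  smi_cache <- new.env(parent = emptyenv())

  frag_smi <- function(vids) {
    k <- paste(sort(vids), collapse = ",")
    hit <- smi_cache[[k]]
    if (!is.null(hit)) return(hit)
    s <- .fragment_smiles(ma, vids)
    assign(k, s, envir = smi_cache)
    s
  }

  consider <- function(map_a) {
    k <- length(map_a)
    if (k < min_heavy || k < best$size) return()
    smi <- frag_smi(map_a)
    if (is.na(smi)) return()
    if (k > best$size || is.null(best$smi) || smi < best$smi) {
      best$size <- k
      best$smi <- smi
    }
  }

  extend <- function(map_a, map_b) {
    if (Sys.time() > deadline) {
      stop(structure(
        class = c("ms2rules_mcs_timeout", "error", "condition"),
        list(message = "time budget exceeded", call = NULL)
      ))
    }
    state <- paste(sort(paste0(map_a, ":", map_b)), collapse = ",")
    if (!is.null(seen[[state]])) return()
    assign(state, TRUE, envir = seen)
    consider(map_a)
    k <- length(map_a)
    if (k + min(na_ - k, nb_ - k) <= best$size) return()
    # frontier: unmapped atoms of `a` bonded to the mapped set
    cand_a <- setdiff(
      which(rowSums(Aa[, map_a, drop = FALSE] > 0L) > 0L), map_a
    )
    for (i in cand_a) {
      for (j in setdiff(which(eb == ea[i]), map_b)) {
        if (all(Aa[i, map_a] == Ab[j, map_b])) {
          extend(c(map_a, i), c(map_b, j))
        }
      }
    }
  }

  for (i in seq_len(na_)) {
    for (j in which(eb == ea[i])) {
      extend(i, j)
    }
  }
  if (is.null(best$smi)) return(NULL)
  tryCatch(substructure(best$smi, source = "cleavage"), error = function(e) NULL)
}
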