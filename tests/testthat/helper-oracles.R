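# Shared fixtures and independent oracles used across test files.

HCL_LOSS <- 35.9767   # monoisotopic neutral mass of HCl, 4 decimals
H2O_LOSS <- 18.0106   # monoisotopic neutral mass of H2O, 4 decimals

# --- hand-built transactions ----------------------------------------------

# A transaction list in the shape build_transactions() produces, from a
# compact description: `features` is a list of character vectors of
# "ftype:value" tokens, `subs` a list of substructure-string vectors.
make_txns <- function(features, subs) {
  stopifnot(length(features) == length(subs))
  txns <- lapply(seq_along(features), function(i) {
    parts <- strsplit(features[[i]], ":", fixed = TRUE)
    list(
      spectrum_id = sprintf("tx_%03d", i),
      features = data.frame(
        ftype = vapply(parts, `[`, character(1L), 1L),
        value = as.numeric(vapply(parts, `[`, character(1L), 2L)),
        stringsAsFactors = FALSE
      ),
      substructures = subs[[i]]
    )
  })
  structure(txns, class = "ms2_transactions", catalog = list())
}

# Random transactions over small feature/substructure alphabets.
random_txns <- function(n, n_feat = 6L, n_sub = 4L, seed = 1L) {
  set.seed(seed)
  feat_pool <- sprintf("Mass:%.4f", 100 + seq_len(n_feat))
  sub_pool <- paste0("S", seq_len(n_sub))
  make_txns(
    features = lapply(seq_len(n), function(i)
      sample(feat_pool, sample(0:4, 1L))),
    subs = lapply(seq_len(n), function(i)
      sample(sub_pool, sample(0:3, 1L)))
  )
}

# --- brute-force rule-mining oracle ---------------------------------------

# Exhaustive double loop over every feature subset of size <= max_body and
# every substructure, counting supports directly. Returns a data frame
# keyed like mine_rules() output.
oracle_mine <- function(txns, max_body = 3L, min_supp_x = 5L, min_tp = 5L) {
  feat_sets <- lapply(txns, function(tx) {
    if (nrow(tx$features) == 0L) return(character(0L))
    unique(paste0(tx$features$ftype, ":", sprintf("%.4f", tx$features$value)))
  })
  sub_sets <- lapply(txns, `[[`, "substructures")
  all_feats <- sort(unique(unlist(feat_sets)))
  all_subs <- sort(unique(unlist(sub_sets)))
  rows <- list()
  for (size in seq_len(min(max_body, length(all_feats)))) {
    combos <- utils::combn(all_feats, size, simplify = FALSE)
    for (body in combos) {
      in_x <- vapply(feat_sets, function(fs) all(body %in% fs), logical(1L))
      if (sum(in_x) < min_supp_x) next
      for (s in all_subs) {
        in_y <- vapply(sub_sets, function(ss) s %in% ss, logical(1L))
        tp <- sum(in_x & in_y)
        if (tp < min_tp) next
        rows[[length(rows) + 1L]] <- data.frame(
          body = paste(sort(body), collapse = ";"), head = s,
          supp_x = sum(in_x), supp_y = sum(in_y), tp = tp,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(body = character(0L), head = character(0L),
                      supp_x = integer(0L), supp_y = integer(0L),
                      tp = integer(0L)))
  }
  df <- do.call(rbind, rows)
  df[order(df$body, df$head), , drop = FALSE]
}

# --- exhaustive common-subgraph oracle ------------------------------------

# Largest connected common subgraph size of two small colored graphs by
# enumerating every connected vertex subset of the smaller graph and
# testing monomorphic embedding into both. Graphs are igraph objects with
# V()$elem and E()$ocolor. Returns the maximum common size (atom count).
oracle_mcs_size <- function(ga, gb) {
  if (igraph::vcount(ga) > igraph::vcount(gb)) {
    tmp <- ga; ga <- gb; gb <- tmp
  }
  n <- igraph::vcount(ga)
  embeds <- function(sub, host) {
    univ <- union(igraph::V(host)$elem, igraph::V(sub)$elem)
    ec <- function(g) if (igraph::ecount(g) == 0L) integer(0L) else igraph::E(g)$ocolor
    igraph::subgraph_isomorphic(
      sub, host, method = "vf2",
      vertex.color1 = match(igraph::V(host)$elem, univ),
      vertex.color2 = match(igraph::V(sub)$elem, univ),
      edge.color1 = ec(host), edge.color2 = ec(sub)
    )
  }
  best <- 0L
  for (size in seq_len(n)) {
    for (vs in utils::combn(n, size, simplify = FALSE)) {
      sg <- igraph::induced_subgraph(ga, vs)
      if (!igraph::is_connected(sg)) next
      if (embeds(sg, ga) && embeds(sg, gb)) best <- max(best, size)
    }
  }
  best
}

# igraph molecular graph from a SMILES, via the package's parser
mol_graph_of <- function(smiles) ms2rules::parse_mol(smiles)$graph

# --- misc ------------------------------------------------------------------

write_test_mgf <- function(lines, path = tempfile(fileext = ".mgf")) {
  writeLines(lines, path)
  path
}

quiet <- function(expr) suppressWarnings(suppressMessages(expr))

# 20 peaks whose pairwise differences are all distinct (quadratic spacing;
# evenly spaced peaks would collapse to 19 distinct differences)
peaks20_distinct <- function() 100 + (1:20)^2 + 0.1234 * (1:20)
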