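# Structure handling: canonicalization, containment, substructure
# generation, similarity and maximum common substructure.

test_that("canonicalization is a fixed point and flags bad input", {
  for (smi in c("OCC", "c1ccccc1", "Cc1ccc(O)cc1", "CC(=O)Nc1ccccc1")) {
    can <- canonical_smiles(smi)
    expect_identical(canonical_smiles(can), can)
  }
  expect_true(is.na(quiet(canonical_smiles("not_a_smiles((("))))
  # different spellings of one molecule agree
  expect_identical(canonical_smiles("OCC"), canonical_smiles("C(O)C"))
})

test_that("containment is monomorphic, element- and bond-order-matched", {
  expect_true(contains_substructure("Cc1ccccc1", "c1ccccc1"))
  expect_false(contains_substructure("c1ccccc1", "Cc1ccccc1"))
  expect_true(contains_substructure("CCO", "CCO"))
  # saturated chain does not embed in an aromatic ring (bond orders differ)
  expect_false(contains_substructure("c1ccccc1", "CC"))
  # double bond must match a double bond
  expect_true(contains_substructure("CC=CC", "C=C"))
  expect_false(contains_substructure("CCCC", "C=C"))
  # element mismatch
  expect_false(contains_substructure("CCO", "CCN"))
})

test_that("triviality filter follows the CHON carbon+oxygen rule", {
  expect_true(is_trivial(substructure("CCCC")))        # C4, CHON
  expect_false(is_trivial(substructure("CCCCO")))      # C4 + O1 = 5
  expect_false(is_trivial(substructure("CCl")))        # halogen: never trivial
  expect_true(is_trivial(substructure("CCN")))         # C2 + N, C+O = 2
  expect_false(is_trivial(substructure("CCCCC")))      # C5
  expect_false(is_trivial(substructure("CCS")))        # sulfur: non-CHON

  # brute-force element-count oracle on a batch of fragments
  frags <- c("CC", "CCC", "CCO", "OCCO", "CCCCC", "CCCCCC", "CCCCO",
             "CCN", "NCCN", "CCCN", "OC(=O)C", "CC(=O)OC", "CCCl", "CCBr",
             "CCSC", "OCC(O)CO", "NC(=O)C", "CCCCCN", "COC", "OCO")
  for (f in frags) {
    mol <- parse_mol(f)
    el <- mol$atoms$elem
    expected <- all(el %in% c("C", "H", "O", "N")) &&
      (sum(el == "C") + sum(el == "O")) < 5
    expect_identical(is_trivial(substructure(f)), expected, label = f)
  }
})

test_that("predefined pattern matching returns embedded patterns only", {
  hits <- predefined_substructures("Cc1ccccc1", c("c1ccccc1", "OCC"))
  expect_equal(vapply(hits, `[[`, character(1), "smiles"),
               canonical_smiles("c1ccccc1"))
  expect_equal(hits[[1]]$source, "predefined")
  expect_length(predefined_substructures("Cc1ccccc1", character(0)), 0L)
  # self-containment
  self_hit <- predefined_substructures("c1ccccc1", "c1ccccc1")
  expect_length(self_hit, 1L)
  # unparsable patterns are skipped, not fatal
  expect_warning(
    hits2 <- predefined_substructures("CCO", c("((bad", "CO")),
    "unparsable"
  )
  expect_length(hits2, 1L)
})

test_that("bond cleavage enumerates acyclic single-bond cuts", {
  # decane: central cut gives two pentyl (C5) fragments; C1-C4 stubs are
  # trivial, so surviving fragments are C5..C9 chains
  frags <- cleavage_substructures("CCCCCCCCCC", max_cuts = 1L)
  smis <- sort(vapply(frags, `[[`, character(1), "smiles"))
  expect_identical(smis, sort(c("CCCCC", "CCCCCC", "CCCCCCC",
                                "CCCCCCCC", "CCCCCCCCC")))
  expect_true(all(vapply(frags, `[[`, character(1), "source") == "cleavage"))

  # benzene has no acyclic bond
  expect_length(cleavage_substructures("c1ccccc1"), 0L)
  # every ethanol fragment is trivial
  expect_length(cleavage_substructures("CCO"), 0L)

  # two cuts free interior fragments that single cuts cannot: every
  # one-cut fragment of phenyloctanoic acid keeps the ring or the acid
  # end, while a double cut isolates plain interior chains
  mol <- "c1ccccc1CCCCCCCC(=O)O"
  one <- vapply(cleavage_substructures(mol, 1L), `[[`, character(1), "smiles")
  two <- vapply(cleavage_substructures(mol, 2L), `[[`, character(1), "smiles")
  expect_true(all(one %in% two))
  expect_true("CCCCCC" %in% setdiff(two, one))
})

test_that("tanimoto is symmetric, 1 on identity, 0 on disjoint fragments", {
  subs <- c("c1ccccc1", "Cc1ccc(O)cc1", "CCCCCC", "CC(=O)NC")
  for (s in subs) expect_equal(tanimoto(s, s), 1.0)
  for (i in 1:3) {
    expect_equal(tanimoto(subs[i], subs[i + 1]), tanimoto(subs[i + 1], subs[i]))
  }
  expect_equal(tanimoto("CCCCCC", "OP(=O)(O)O"), 0)

  # independent path-set oracle: enumerate simple paths with igraph,
  # canonicalize direction, hash with the same public rolling hash
  path_set <- function(smiles, nbits = 1024L) {
    g <- mol_graph_of(smiles)
    elem <- igraph::V(g)$elem
    strs <- character(0)
    for (v in seq_len(igraph::vcount(g))) {
      sp <- igraph::all_simple_paths(g, from = v, cutoff = 7)
      for (p in sp) {
        p <- as.integer(p)
        if (length(p) < 2) next
        eids <- igraph::get_edge_ids(g, rbind(p[-length(p)], p[-1]))
        bo <- igraph::E(g)$order[eids]
        fwd <- paste0(elem[p[1]],
                      paste0(bo, elem[p[-1]], collapse = ""))
        rp <- rev(p)
        bo_r <- rev(bo)
        bwd <- paste0(elem[rp[1]],
                      paste0(bo_r, elem[rp[-1]], collapse = ""))
        strs <- c(strs, min(fwd, bwd))
      }
    }
    strs <- unique(strs)
    hash1 <- function(s) {
      h <- 0
      for (cc in utf8ToInt(s)) h <- (h * 31 + cc) %% 1048573
      as.integer(h %% nbits) + 1L
    }
    unique(vapply(strs, hash1, integer(1)))
  }
  a <- path_set("c1ccccc1")
  b <- path_set("c1ccncc1")
  expect_equal(tanimoto("c1ccccc1", "c1ccncc1"),
               length(intersect(a, b)) / length(union(a, b)))
})

test_that("mcs finds the exact maximum connected common subgraph", {
  expect_identical(mcs("CCO", "CCO")$smiles, canonical_smiles("CCO"))
  m <- mcs("c1ccccc1", "Cc1ccccc1")
  expect_identical(m$smiles, canonical_smiles("c1ccccc1"))
  # exhaustive common-subgraph oracle agrees on the size
  expect_equal(m$n_heavy,
               oracle_mcs_size(mol_graph_of("c1ccccc1"),
                               mol_graph_of("Cc1ccccc1")))
  # no 2-atom overlap between a C-Cl stub and an amino alcohol
  expect_null(mcs("CCl", "OCCN"))
  # oracle check on a heteroatom pair
  m2 <- mcs("CCNC=O", "CCCNC")
  expect_equal(m2$n_heavy,
               oracle_mcs_size(mol_graph_of("CCNC=O"), mol_graph_of("CCCNC")))
  # the MCS embeds in both parents
  for (pair in list(c("Cc1ccc(O)cc1", "CCc1ccc(O)cc1"),
                    c("CCCCCCC", "CCCCO"),
                    c("Clc1ccccc1", "CCCl"))) {
    mm <- mcs(pair[1], pair[2])
    expect_true(contains_substructure(pair[1], mm), label = paste(pair, collapse = "/"))
    expect_true(contains_substructure(pair[2], mm), label = paste(pair, collapse = "/"))
  }
})

test_that("mcs respects its time budget on large pairs", {
  t0 <- Sys.time()
  expect_warning(
    res <- mcs("CC12CCC3C(CCC4=CC(=O)CCC34C)C1CCC2O",
               "CC12CCC3C(CCC4CC(=O)CCC34)C1CCC2=O",
               time_budget = 0.5),
    "budget"
  )
  expect_null(res)
  expect_lt(as.numeric(difftime(Sys.time(), t0, units = "secs")), 10)
})
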