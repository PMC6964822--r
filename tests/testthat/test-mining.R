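# Rule mining: transaction building, exact support counting, oracle
# equivalence and the confusion-matrix identities.

test_that("planted single-feature rule recovers designed precision/recall", {
  # feature f in exactly the 10 spectra whose molecules contain S
  # (10 of 40 compounds): a perfect rule
  txns <- make_txns(
    features = c(rep(list("MDiff:35.9767"), 10), rep(list(character(0)), 30)),
    subs = c(rep(list("S"), 10), rep(list("T"), 30))
  )
  rules <- mine_rules(txns, min_supp_x = 5, min_tp = 5)
  expect_equal(nrow(rules), 1L)
  expect_equal(rules$precision, 1.0)
  expect_equal(rules$recall, 1.0)
  expect_equal(rules$supp_x, 10L)
  expect_equal(rules$supp_y, 10L)
  expect_equal(rules$tp, 10L)
})

test_that("partial co-occurrence yields the hand-counted statistics", {
  # f in 10 spectra, S in 20 compounds, co-occurrence 8
  txns <- make_txns(
    features = c(rep(list("Mass:120.5000"), 10), rep(list(character(0)), 30)),
    subs = c(rep(list("S"), 8), rep(list(character(0)), 2),
             rep(list("S"), 12), rep(list(character(0)), 18))
  )
  rules <- mine_rules(txns)
  expect_equal(rules$precision, 0.8)
  expect_equal(rules$recall, 0.4)
  # below min_tp the rule disappears
  txns2 <- make_txns(
    features = c(rep(list("Mass:120.5000"), 10), rep(list(character(0)), 10)),
    subs = c(rep(list("S"), 4), rep(list(character(0)), 6), rep(list("S"), 10))
  )
  expect_equal(nrow(mine_rules(txns2, min_tp = 5)), 0L)
})

test_that("mining equals the exhaustive double-loop oracle", {
  for (seed in 1:4) {
    txns <- random_txns(40, n_feat = 5, n_sub = 4, seed = seed)
    mined <- mine_rules(txns, max_body = 3, min_supp_x = 5, min_tp = 5)
    oracle <- oracle_mine(txns, max_body = 3, min_supp_x = 5, min_tp = 5)
    mined_o <- as.data.frame(mined[order(mined$body, mined$head),
                                   c("body", "head", "supp_x", "supp_y", "tp")])
    rownames(mined_o) <- rownames(oracle) <- NULL
    expect_equal(mined_o, oracle, label = paste("seed", seed))
  }
})

test_that("rule identities and anti-monotonicity hold", {
  txns <- random_txns(50, n_feat = 6, n_sub = 5, seed = 9)
  rules <- mine_rules(txns, min_supp_x = 3, min_tp = 3)
  expect_gt(nrow(rules), 0)
  expect_equal(rules$precision * rules$supp_x, rules$tp)
  expect_equal(rules$recall * rules$supp_y, rules$tp)
  expect_true(all(rules$tp <= pmin(rules$supp_x, rules$supp_y)))
  # raising thresholds never adds rules
  stricter <- mine_rules(txns, min_supp_x = 5, min_tp = 3)
  expect_true(all(paste(stricter$body, stricter$head) %in%
                    paste(rules$body, rules$head)))
  stricter2 <- mine_rules(txns, min_supp_x = 3, min_tp = 5)
  expect_true(all(paste(stricter2$body, stricter2$head) %in%
                    paste(rules$body, rules$head)))
})

test_that("multi-feature bodies are mined with conjunctive support", {
  # f1+f2 together only in S-compounds; f1 alone is widespread
  txns <- make_txns(
    features = c(rep(list(c("Mass:100.1000", "MDiff:18.0106")), 6),
                 rep(list("Mass:100.1000"), 14)),
    subs = c(rep(list("S"), 6), rep(list(character(0)), 14))
  )
  rules <- mine_rules(txns, min_supp_x = 5, min_tp = 5)
  pair_rule <- rules[grepl(";", rules$body), ]
  expect_equal(nrow(pair_rule), 1L)
  expect_equal(pair_rule$body, "MDiff:18.0106;Mass:100.1000")
  expect_equal(pair_rule$precision, 1.0)
  single_rule <- rules[rules$body == "Mass:100.1000", ]
  expect_equal(single_rule$precision, 6 / 20)
})

test_that("build_transactions joins features with generated substructures", {
  recs <- list(
    spectrum_record("s1", data.frame(mass = c(200.5, 100.5), intensity = 1),
                    structure = "Clc1ccccc1",
                    tree_edges = data.frame(parent_mass = 200.5, child_mass = 100.5)),
    spectrum_record("s2", data.frame(mass = c(210.5, 110.5), intensity = 1),
                    structure = "Cc1ccc(O)cc1",
                    tree_edges = data.frame(parent_mass = 210.5, child_mass = 110.5)),
    spectrum_record("s3", data.frame(mass = c(220.5, 120.5), intensity = 1),
                    structure = "CCCCCCCCCC",
                    tree_edges = data.frame(parent_mass = 220.5, child_mass = 120.5))
  )
  lib <- spectral_library(recs, "target")
  feats <- extract_features(lib)
  txns <- build_transactions(lib, feats, patterns = c("c1ccccc1", "CCl"))
  expect_length(txns, 3L)
  expect_true(canonical_smiles("c1ccccc1") %in% txns[[1]]$substructures)
  expect_true(canonical_smiles("CCl") %in% txns[[1]]$substructures)
  expect_false(canonical_smiles("c1ccccc1") %in% txns[[3]]$substructures)
  # decane contributes cleavage chains
  expect_true("CCCCC" %in% txns[[3]]$substructures)
  # unparsable structure: record excluded with a warning
  bad <- spectral_library(c(recs, list(
    spectrum_record("s4", data.frame(mass = 100, intensity = 1),
                    structure = "xx((bad")
  )), "target")
  feats_b <- rbind(feats, data.frame(spectrum_id = "s4", ftype = "Mass",
                                     value = 100))
  expect_warning(txns_b <- build_transactions(bad, feats_b,
                                              patterns = "c1ccccc1"),
                 "parsable")
  expect_length(txns_b, 3L)
})

test_that("evaluate_rules reproduces training statistics on its own data", {
  txns <- random_txns(30, seed = 21)
  rules <- mine_rules(txns, min_supp_x = 3, min_tp = 3)
  ev <- evaluate_rules(rules, txns, min_tp = 3)
  expect_equal(ev$tp, rules$tp)
  expect_equal(ev$precision, rules$precision)
  expect_equal(ev$recall, rules$recall)
  expect_equal(ev$tp + ev$fp, ev$supp_x)
  expect_equal(ev$tp + ev$fn, ev$supp_y)
  expect_equal(ev$tp + ev$fp + ev$fn + ev$tn, rep(30L, nrow(ev)))
})

test_that("evaluation on a hand-counted six-transaction set is exact", {
  txns <- make_txns(
    features = list("Mass:100.1000", "Mass:100.1000", "Mass:100.1000",
                    character(0), character(0), character(0)),
    subs = list("S", "S", character(0), "S", character(0), character(0))
  )
  rules <- data.frame(rule_id = 1L, origin = "target", body = "Mass:100.1000",
                      head = "S", supp_x = 0L, supp_y = 0L, tp = 0L,
                      precision = 0, recall = 0, stringsAsFactors = FALSE)
  class(rules) <- c("ms2_rules", "data.frame")
  ev <- evaluate_rules(rules, txns, min_tp = 5)
  expect_equal(ev$tp, 2L)       # t1, t2
  expect_equal(ev$fp, 1L)       # t3
  expect_equal(ev$fn, 1L)       # t4
  expect_equal(ev$tn, 2L)       # t5, t6
  expect_false(ev$evaluable)    # tp < 5
  # a rule whose body never occurs is flagged with undefined precision
  rules$body <- "Mass:999.9999"
  ev2 <- evaluate_rules(rules, txns)
  expect_equal(ev2$supp_x, 0L)
  expect_true(is.na(ev2$precision))
  expect_false(ev2$evaluable)
})

test_that("rule databases round-trip through TSV with config fingerprints", {
  txns <- random_txns(30, seed = 2)
  rules <- mine_rules(txns, min_supp_x = 3, min_tp = 3)
  cfg <- pipeline_config()
  path <- tempfile(fileext = ".tsv")
  write_rule_db(rules, path, config = cfg)
  back <- read_rule_db(path)
  expect_equal(attr(back, "config_fingerprint"), config_fingerprint(cfg))
  expect_equal(back$body, rules$body)
  expect_equal(back$recall, rules$recall, tolerance = 1e-12)
})
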