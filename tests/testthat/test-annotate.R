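# Query annotation: rule matching, the three aggregation modes and motif
# annotation.

rule_df <- function(bodies, heads, recalls, ids = seq_along(bodies)) {
  df <- data.frame(
    rule_id = ids, origin = "target", body = bodies, head = heads,
    supp_x = 10L, supp_y = 10L, tp = as.integer(round(recalls * 10)),
    precision = 0.5, recall = recalls, stringsAsFactors = FALSE
  )
  class(df) <- c("ms2_rules", "data.frame")
  df
}

query_of <- function(...) {
  v <- c(...)
  data.frame(ftype = names(v), value = unname(v), stringsAsFactors = FALSE)
}

test_that("rule matching is conjunctive within the ppm window", {
  db <- rule_df(
    bodies = c("Mass:160.0762", "MDiff:18.0106;Mass:160.0762", "MDiff:35.9767"),
    heads = c("c1ccccc1", "c1ccccc1", "CCl"),
    recalls = c(0.6, 0.4, 0.9)
  )
  q1 <- query_of(Mass = 160.0762)
  m1 <- match_rules(q1, db)
  expect_equal(m1$rule_id, 1L)          # 2-feature body not satisfied
  q2 <- query_of(Mass = 160.0762, MDiff = 18.0106)
  m2 <- match_rules(q2, db)
  expect_setequal(m2$rule_id, c(1L, 2L))
  expect_equal(m2$recall, sort(m2$recall, decreasing = TRUE))
  # 30 ppm away: no match at 20 ppm
  q3 <- query_of(MDiff = 35.9767 * (1 + 30e-6))
  expect_equal(nrow(match_rules(q3, db, ppm = 20)), 0L)
  expect_equal(match_rules(q3, db, ppm = 40)$rule_id, 3L)
  # ppm -> 0 reduces to exact discretized equality
  q4 <- query_of(MDiff = 35.9767)
  expect_equal(match_rules(q4, db, ppm = 0)$rule_id, 3L)
  q5 <- query_of(MDiff = 35.9768)
  expect_equal(nrow(match_rules(q5, db, ppm = 0)), 0L)
})

test_that("naive aggregation sums recall over identical heads", {
  db <- rule_df(
    bodies = c("Mass:100.1000", "MDiff:18.0106", "Mass:120.2000"),
    heads = c("c1ccccc1", "c1ccccc1", "CCCCCC"),
    recalls = c(0.6, 0.3, 0.5)
  )
  m <- match_rules(query_of(Mass = 100.1, MDiff = 18.0106, Mass = 120.2), db)
  rec <- aggregate_naive(m)
  expect_equal(nrow(rec), 2L)
  expect_equal(rec$score[rec$substructure == "c1ccccc1"], 0.9)
  expect_equal(rec$rank, 1:2)
  expect_true(all(diff(rec$score) <= 0))
  expect_equal(nrow(aggregate_naive(m[0, ])), 0L)
})

test_that("exhaustive aggregation merges analogous rules through the MCS", {
  # cresol and ethylphenol heads are analogous (Tanimoto > 0.5, shared
  # phenol core); the aliphatic head is unrelated and passes through
  cresol <- canonical_smiles("Cc1ccc(O)cc1")
  ethylphenol <- canonical_smiles("CCc1ccc(O)cc1")
  db <- rule_df(
    bodies = c("Mass:108.0575", "Mass:122.0732", "Mass:114.1000"),
    heads = c(cresol, ethylphenol, "CCCCCCCC"),
    recalls = c(0.5, 0.4, 0.3)
  )
  expect_gt(tanimoto(cresol, ethylphenol), 0.5)
  m <- match_rules(query_of(Mass = 108.0575, Mass = 122.0732, Mass = 114.1), db)
  rec <- aggregate_exhaustive(m, min_heavy = 5)
  core <- rec[rec$substructure == cresol, ]   # MCS(cresol, ethylphenol)
  expect_equal(nrow(core), 1L)
  expect_equal(core$score, 0.9)               # 0.5 + 0.4 via the MCS
  expect_equal(core$rule_ids, "1;2")
  octane <- rec[rec$substructure == "CCCCCCCC", ]
  expect_equal(octane$score, 0.3)             # pass-through

  # identical heads: MCS is the head itself, recalls sum
  db2 <- rule_df(c("Mass:78.0468", "MDiff:18.0106"),
                 c("c1ccccc1", "c1ccccc1"), c(0.4, 0.5))
  m2 <- match_rules(query_of(Mass = 78.0468, MDiff = 18.0106), db2)
  rec2 <- aggregate_exhaustive(m2, min_heavy = 5)
  expect_equal(rec2$substructure, "c1ccccc1")
  expect_equal(rec2$score, 0.9)

  # heads below the similarity threshold stay separate
  db3 <- rule_df(c("Mass:78.0468", "Mass:114.1000"),
                 c("c1ccccc1", "CCCCCCCC"), c(0.5, 0.3))
  m3 <- match_rules(query_of(Mass = 78.0468, Mass = 114.1), db3)
  rec3 <- aggregate_exhaustive(m3, min_heavy = 5)
  expect_setequal(rec3$substructure, c("c1ccccc1", "CCCCCCCC"))
})

test_that("small recommendations are filtered at reporting time", {
  db <- rule_df("MDiff:35.9767", "CCl", 0.9)
  m <- match_rules(query_of(MDiff = 35.9767), db)
  expect_equal(nrow(aggregate_exhaustive(m, min_heavy = 5)), 0L)  # 2 atoms
  expect_equal(nrow(aggregate_exhaustive(m, min_heavy = 1)), 1L)
})

test_that("fast aggregation equals exhaustive for <= 20 matches", {
  set.seed(3)
  heads <- c("c1ccccc1", "Cc1ccccc1", "CCc1ccccc1", "Oc1ccccc1", "CCCCCCCC")
  db <- rule_df(
    bodies = sprintf("Mass:%.4f", 100 + 1:15),
    heads = rep(heads, 3),
    recalls = round(runif(15, 0.2, 0.9), 2)
  )
  q <- data.frame(ftype = "Mass", value = 100 + 1:15)
  m <- match_rules(q, db)
  expect_equal(nrow(m), 15L)
  expect_equal(aggregate_fast(m, min_heavy = 5),
               aggregate_exhaustive(m, min_heavy = 5))
})

test_that("fast aggregation keeps only the 20 highest-recall matches", {
  db <- rule_df(
    bodies = sprintf("Mass:%.4f", 100 + 1:25),
    heads = rep("c1ccccc1", 25),
    recalls = seq(0.99, 0.51, length.out = 25)
  )
  m <- match_rules(data.frame(ftype = "Mass", value = 100 + 1:25), db)
  rec <- aggregate_fast(m, min_heavy = 5)
  used <- as.integer(strsplit(rec$rule_ids, ";")[[1]])
  expect_length(used, 20L)
  expect_true(all(used %in% 1:20))  # the 5 lowest-recall rules dropped
  expect_equal(rec$score, sum(db$recall[1:20]))
})

test_that("recommendation scores equal the sum of contributing recalls", {
  set.seed(12)
  heads <- c("c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "CCCCCCCC", "CCCCCCN")
  db <- rule_df(
    bodies = sprintf("MDiff:%.4f", 30 + 1:12),
    heads = sample(heads, 12, replace = TRUE),
    recalls = round(runif(12, 0.1, 0.95), 3)
  )
  m <- match_rules(data.frame(ftype = "MDiff", value = 30 + 1:12), db)
  for (rec in list(aggregate_naive(m), aggregate_exhaustive(m, min_heavy = 2),
                   aggregate_fast(m, min_heavy = 2))) {
    for (i in seq_len(nrow(rec))) {
      ids <- as.integer(strsplit(rec$rule_ids[i], ";")[[1]])
      expect_equal(rec$score[i], sum(db$recall[db$rule_id %in% ids]))
    }
    expect_true(all(diff(rec$score) <= 0))
  }
})

test_that("motif annotation selects by recall and falls back to MCS on ties", {
  # single matching rule: its head is the annotation
  db1 <- rule_df("Mass:172.0757", canonical_smiles("c1ccc2[nH]ccc2c1"), 0.6)
  motif <- data.frame(ftype = "Mass", value = 172.0757, probability = 0.9)
  ann1 <- annotate_motif(motif, db1)
  expect_equal(ann1$status, "ok")
  expect_equal(ann1$substructure, canonical_smiles("c1ccc2[nH]ccc2c1"))

  # same body, different recalls: the higher-recall head wins
  db2 <- rule_df(c("Mass:172.0757", "Mass:172.0757"),
                 c("Cc1ccccc1", "CCCCCC"), c(0.6, 0.4), ids = 1:2)
  ann2 <- annotate_motif(motif, db2)
  expect_equal(ann2$substructure, canonical_smiles("Cc1ccccc1"))
  expect_equal(ann2$rule_ids, 1L)

  # tie on recall: report the MCS of the tied heads
  db3 <- rule_df(c("Mass:172.0757", "Mass:172.0757"),
                 c("Cc1ccccc1", "CCc1ccccc1"), c(0.5, 0.5), ids = 1:2)
  ann3 <- annotate_motif(motif, db3)
  expect_equal(ann3$substructure, mcs("Cc1ccccc1", "CCc1ccccc1")$smiles)

  # only the top_k most probable features are used
  db4 <- rule_df("Mass:500.0000", "c1ccccc1", 0.9)
  motif4 <- data.frame(
    ftype = "Mass",
    value = c(1:60 + 0.5, 500.0),
    probability = c(seq(1, 0.5, length.out = 60), 0.01)
  )
  ann4 <- annotate_motif(motif4, db4, top_k = 50)
  expect_equal(ann4$status, "no annotation")
  expect_true(is.na(ann4$substructure))
})
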