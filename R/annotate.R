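# Query annotation.
#
# A query feature set is matched against the rule database (a rule matches
# when every body feature finds a query feature within the ppm tolerance,
# with feature types agreeing), matched rules are ranked by recall, and
# analogous rules (head Tanimoto > 0.5) are merged into maximum-common-
# substructure recommendations scored by summed recall.

#' Match query features against a rule database
#'
#' A rule matches when each of its body features has at least one query
#' feature of the same type within the ppm window (conjunctive semantics:
#' a 2-feature body needs both features). Matches are sorted by recall,
#' descending.
#'
#' @param query Feature data frame (`ftype`, `value`), e.g. from
#'   [extract_query_features()].
#' @param rules An `ms2_rules` data frame.
#' @param ppm Mass tolerance in ppm.
#' @return The matching subset of `rules`, sorted by recall descending,
#'   with a `matched_features` list-column naming the query feature
#'   matched to each body item.
#' @export
match_rules <- function(query, rules, ppm = 20) {
  if (nrow(rules) == 0L) {
    out <- as.data.frame(rules)
    out$matched_features <- list()
    return(out)
  }
  tokens <- unique(unlist(strsplit(rules$body, ";", fixed = TRUE)))
  tok_parts <- strsplit(tokens, ":", fixed = TRUE)
  tok_type <- vapply(tok_parts, `[`, character(1L), 1L)
  tok_value <- as.numeric(vapply(tok_parts, `[`, character(1L), 2L))
  # first matching query feature per body token (NA when none)
  tok_match <- vapply(seq_along(tokens), function(i) {
    hit <- which(features_match(query$ftype, query$value,
                                tok_type[i], tok_value[i], ppm = ppm))
    if (length(hit) == 0L) NA_character_
    else paste0(query$ftype[hit[1L]], ":", fmt_mass(query$value[hit[1L]]))
  }, character(1L))
  names(tok_match) <- tokens

  body_toks <- strsplit(rules$body, ";", fixed = TRUE)
  ok <- vapply(body_toks, function(tk) !anyNA(tok_match[tk]), logical(1L))
  out <- rules[ok, , drop = FALSE]
  matched <- lapply(body_toks[ok], function(tk) unname(tok_match[tk]))
  ord <- order(-out$recall, out$rule_id)
  out <- out[ord, , drop = FALSE]
  out$matched_features <- matched[ord]
  rownames(out) <- NULL
  out
}

.sub_heavy <- function(smiles) {
  vapply(smiles, function(s) {
    tryCatch(nrow(parse_mol(s)$atoms), error = function(e) 0L)
  }, integer(1L))
}

.finish_recommendations <- function(sub, score, rule_ids, min_heavy) {
  if (length(sub) == 0L) {
    return(data.frame(rank = integer(0L), substructure = character(0L),
                      score = numeric(0L), n_rules = integer(0L),
                      rule_ids = character(0L), stringsAsFactors = FALSE))
  }
  heavy <- .sub_heavy(sub)
  keep <- heavy >= min_heavy
  df <- data.frame(
    substructure = sub[keep],
    score = score[keep],
    n_rules = lengths(rule_ids[keep]),
    rule_ids = vapply(rule_ids[keep], function(x)
      paste(sort(x), collapse = ";"), character(1L)),
    stringsAsFactors = FALSE
  )
  heavy <- heavy[keep]
  ord <- order(-df$score, -heavy, df$substructure)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rank = seq_len(nrow(df)), df)
  rownames(df) <- NULL
  df
}

#' Naive aggregation: combine rules with identical heads
#'
#' Groups matched rules by canonical head; each recommendation's score is
#' the summed recall of its rules (each rule counted once).
#'
#' @param matches Output of [match_rules()].
#' @param min_heavy Minimum heavy-atom count for a reportable
#'   recommendation (1 = report everything).
#' @return Recommendation data frame (`rank`, `substructure`, `score`,
#'   `n_rules`, `rule_ids`), scores non-increasing with rank.
#' @export
aggregate_naive <- function(matches, min_heavy = 1L) {
  if (nrow(matches) == 0L) return(.finish_recommendations(character(0L), numeric(0L), list(), min_heavy))
  grp <- split(seq_len(nrow(matches)), matches$head)
  sub <- names(grp)
  score <- vapply(grp, function(i) sum(matches$recall[i][!duplicated(matches$rule_id[i])]),
                  numeric(1L))
  ids <- lapply(grp, function(i) unique(matches$rule_id[i]))
  .finish_recommendations(sub, unname(score), unname(ids), min_heavy)
}

#' Exhaustive aggregation: merge analogous rules via MCS
#'
#' Every unordered pair of matched rules whose heads have Tanimoto
#' similarity above `sim_threshold` is an "analogous" pair; the maximum
#' common substructure of each pair is computed and identical canonical
#' MCS strings are merged, the contributing rule set of an MCS being the
#' union over all pairs that produced it. A rule's recall counts once per
#' recommendation even when the rule appears in several pairs. Rules in no
#' analogous pair pass through with their own head. Recommendations with
#' fewer than `min_heavy` heavy atoms are dropped (small fragments are
#' uninformative at reporting time).
#'
#' @param matches Output of [match_rules()].
#' @param sim_threshold Tanimoto threshold defining analogous rules.
#' @param min_heavy Minimum heavy atoms of a reported recommendation.
#' @param mcs_budget Per-pair MCS time budget in seconds.
#' @return Recommendation data frame as in [aggregate_naive()].
#' @export
aggregate_exhaustive <- function(matches, sim_threshold = 0.5, min_heavy = 5L,
                                 mcs_budget = 1) {
  n <- nrow(matches)
  if (n == 0L) return(.finish_recommendations(character(0L), numeric(0L), list(), min_heavy))
  heads <- matches$head
  uh <- unique(heads)
  sim <- matrix(0, length(uh), length(uh), dimnames = list(uh, uh))
  if (length(uh) >= 2L) {
    for (i in seq_len(length(uh) - 1L)) {
      for (j in seq((i + 1L), length(uh))) {
        sim[i, j] <- sim[j, i] <- tanimoto(uh[i], uh[j])
      }
    }
  }
  diag(sim) <- 1

  mcs_rules <- list()   # canonical MCS smiles -> rule ids
  in_pair <- rep(FALSE, n)
  if (n >= 2L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq((i + 1L), n)) {
        if (sim[heads[i], heads[j]] <= sim_threshold) next
        in_pair[c(i, j)] <- TRUE
        m <- mcs(heads[i], heads[j], time_budget = mcs_budget)
        if (is.null(m)) next  # no common core or budget exceeded: pair skipped
        mcs_rules[[m$smiles]] <- unique(c(mcs_rules[[m$smiles]],
                                          matches$rule_id[c(i, j)]))
      }
    }
  }
  # pass-through for rules in no analogous pair
  solo <- which(!in_pair)
  solo_grp <- split(matches$rule_id[solo], heads[solo])
  sub <- c(names(mcs_rules), names(solo_grp))
  ids <- c(unname(mcs_rules), lapply(solo_grp, unique))
  score <- vapply(ids, function(rid)
    sum(matches$recall[match(unique(rid), matches$rule_id)]), numeric(1L))
  .finish_recommendations(sub, score, ids, min_heavy)
}

#' Fast aggregation: MCS on the 20 most sensitive rules
#'
#' [aggregate_exhaustive()] applied to the 20 highest-recall matches
#' (ties broken by rule id). Identical to the exhaustive mode when at most
#' 20 rules matched.
#'
#' @inheritParams aggregate_exhaustive
#' @param top Number of rules retained.
#' @return Recommendation data frame.
#' @export
aggregate_fast <- function(matches, sim_threshold = 0.5, min_heavy = 5L,
                           mcs_budget = 1, top = 20L) {
  if (nrow(matches) > top) {
    ord <- order(-matches$recall, matches$rule_id)
    matches <- matches[ord[seq_len(top)], , drop = FALSE]
  }
  aggregate_exhaustive(matches, sim_threshold = sim_threshold,
                       min_heavy = min_heavy, mcs_budget = mcs_budget)
}

#' Annotate a co-occurring-feature motif with a substructure
#'
#' Takes the `top_k` most probable motif features, matches them against
#' the rule database (all body features of a rule must occur among the
#' selected motif features, types agreeing within `ppm`), and reduces the
#' matched rules: among rules sharing the same body feature set only the
#' highest-recall rule is kept; when recall ties, the MCS of the tied
#' heads is used. The reported annotation is the most frequent canonical
#' substructure across the selected rules.
#'
#' @param motif_features Data frame with columns `ftype`, `value`,
#'   `probability`.
#' @param rules An `ms2_rules` data frame.
#' @param top_k Number of motif features used.
#' @param ppm Mass tolerance in ppm.
#' @param mcs_budget Per-pair MCS time budget in seconds.
#' @return A list with `status` (`"ok"` or `"no annotation"`),
#'   `substructure` (canonical SMILES or `NA`), `candidates` (per-body
#'   selection table) and `rule_ids`.
#' @export
annotate_motif <- function(motif_features, rules, top_k = 50L, ppm = 20,
                           mcs_budget = 1) {
  stopifnot(all(c("ftype", "value", "probability") %in% names(motif_features)))
  mf <- motif_features[order(-motif_features$probability), , drop = FALSE]
  mf <- mf[seq_len(min(top_k, nrow(mf))), , drop = FALSE]
  matches <- match_rules(mf[c("ftype", "value")], rules, ppm = ppm)
  if (nrow(matches) == 0L) {
    return(list(status = "no annotation", substructure = NA_character_,
                candidates = NULL, rule_ids = integer(0L)))
  }
  picks <- lapply(split(seq_len(nrow(matches)), matches$body), function(idx) {
    top_recall <- max(matches$recall[idx])
    tied <- idx[matches$recall[idx] == top_recall]
    sub <- matches$head[tied[1L]]
    if (length(tied) > 1L) {
      for (k in tied[-1L]) {
        m <- mcs(sub, matches$head[k], time_budget = mcs_budget)
        if (is.null(m)) next
        sub <- m$smiles
      }
    }
    list(substructure = sub, rule_ids = matches$rule_id[tied],
         recall = top_recall)
  })
  subs <- vapply(picks, `[[`, character(1L), "substructure")
  tab <- sort(table(subs), decreasing = TRUE)
  winner <- names(tab)[1L]
  list(
    status = "ok",
    substructure = winner,
    candidates = data.frame(
      body = names(picks),
      substructure = unname(subs),
      recall = vapply(picks, `[[`, numeric(1L), "recall"),
      stringsAsFactors = FALSE
    ),
    rule_ids = sort(unique(unlist(lapply(
      picks[subs == winner], `[[`, "rule_ids"
    ))))
  )
}
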