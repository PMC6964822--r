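# Association rule mining.
#
# Transactions join a compound's spectral feature set with its generated
# substructure set. Rules have a body of 1-3 features and a single
# substructure head; support, true-positive count, precision and recall
# are exact counts over the transactions. Mining enumerates frequent
# feature itemsets first (levelwise, on transaction-id lists) and then
# crosses them with substructure heads, so bodies can never contain
# substructures nor heads more than one item.

#' Build transactions from a labeled library
#'
#' One transaction per record: the record's features joined with the
#' substructures generated from its structure (predefined patterns plus
#' bond cleavage, both filtered for triviality and minimum size). Records
#' whose structure does not parse are excluded with a warning.
#'
#' @param lib A structure-labeled [spectral_library()] (merge it first if
#'   several spectra may share one structure).
#' @param feats Feature data frame (`spectrum_id`, `ftype`, `value`) as
#'   returned by [extract_features()].
#' @param patterns Character vector of predefined pattern SMILES (see
#'   [read_pattern_file()]).
#' @param max_cuts Bond-disconnection depth for [cleavage_substructures()].
#' @param cleavage Set `FALSE` to skip the cleavage route.
#' @return A list of transactions (class `ms2_transactions`); each element
#'   has `spectrum_id`, `features` (data frame) and `substructures`
#'   (character vector of canonical SMILES). The attribute `"catalog"`
#'   maps SMILES to their `ms2_substructure` objects.
#' @export
build_transactions <- function(lib, feats, patterns = character(0L),
                               max_cuts = 2L, cleavage = TRUE) {
  stopifnot(inherits(lib, "ms2_library"))
  patterns <- as.character(patterns)  # force now: lazy errors must not be
                                      # mistaken for unparsable structures
  catalog <- new.env(parent = emptyenv())
  sub_cache <- new.env(parent = emptyenv())
  txns <- list()
  n_bad <- 0L
  for (rec in lib$records) {
    smi <- rec$structure
    subs <- character(0L)
    if (!is.na(smi)) {
      key <- smi
      hit <- sub_cache[[key]]
      if (is.null(hit)) {
        hit <- tryCatch({
          sl <- predefined_substructures(smi, patterns)
          if (cleavage) sl <- c(sl, cleavage_substructures(smi, max_cuts = max_cuts))
          sl
        }, error = function(e) NULL)
        if (is.null(hit)) {
          n_bad <- n_bad + 1L
          assign(key, "unparsable", envir = sub_cache)
          hit <- "unparsable"
        } else {
          assign(key, hit, envir = sub_cache)
        }
      }
      if (identical(hit, "unparsable")) next
      for (s in hit) assign(s$smiles, s, envir = catalog)
      subs <- unique(vapply(hit, `[[`, character(1L), "smiles"))
    } else {
      n_bad <- n_bad + 1L
      next
    }
    fr <- feats[feats$spectrum_id == rec$spectrum_id, c("ftype", "value"), drop = FALSE]
    txns[[length(txns) + 1L]] <- list(
      spectrum_id = rec$spectrum_id,
      features = fr,
      substructures = subs
    )
  }
  if (n_bad > 0L) {
    warning(n_bad, " record(s) without parsable structure excluded",
            call. = FALSE)
  }
  structure(txns, class = "ms2_transactions",
            catalog = as.list(catalog))
}

#' @export
print.ms2_transactions <- function(x, ...) {
  cat("<ms2_transactions> ", length(x), " transactions, ",
      length(attr(x, "catalog")), " distinct substructures\n", sep = "")
  invisible(x)
}

# body key: sorted "ftype:value" tokens joined by ";"
.body_key <- function(tokens) paste(sort(tokens), collapse = ";")

#' Parse a rule body string into a feature data frame
#'
#' @param body Body string of semicolon-joined `ftype:value` tokens.
#' @return Data frame with columns `ftype`, `value`.
#' @export
parse_body <- function(body) {
  toks <- strsplit(body, ";", fixed = TRUE)[[1L]]
  parts <- strsplit(toks, ":", fixed = TRUE)
  data.frame(
    ftype = vapply(parts, `[`, character(1L), 1L),
    value = as.numeric(vapply(parts, `[`, character(1L), 2L)),
    stringsAsFactors = FALSE
  )
}

#' Mine feature => substructure association rules
#'
#' Enumerates frequent feature itemsets of size up to `max_body` with
#' support at least `min_supp_x`, crosses each with every substructure,
#' and keeps rules whose true-positive count reaches `min_tp`. Precision
#' (`tp / supp_x`) and recall (`tp / supp_y`) are exact counts over the
#' transactions; `supp_y` counts the compounds (transactions) containing
#' the head substructure. Rules are ordered by recall, then precision
#' (both descending), body size and head SMILES, and numbered in that
#' order, so rule ids are stable across runs.
#'
#' @param txns Transactions from [build_transactions()].
#' @param max_body Maximum body size (1-3).
#' @param min_supp_x Minimum number of spectra containing the body.
#' @param min_tp Minimum true-positive count.
#' @param origin Label recorded on every rule: `"target"` or `"decoy"`.
#' @return A data frame of class `ms2_rules` with columns `rule_id`,
#'   `origin`, `body`, `head`, `supp_x`, `supp_y`, `tp`, `precision`,
#'   `recall`.
#' @export
mine_rules <- function(txns, max_body = 3L, min_supp_x = 5L, min_tp = 5L,
                       origin = c("target", "decoy")) {
  origin <- match.arg(origin)
  stopifnot(length(txns) >= 1L, max_body %in% 1:3)
  n <- length(txns)

  feat_tokens <- lapply(txns, function(tx) unique(feature_key(tx$features)))

  # tid lists per single feature
  all_tok <- unlist(feat_tokens, use.names = FALSE)
  tid1 <- split(rep(seq_len(n), lengths(feat_tokens)), all_tok)
  tid1 <- tid1[lengths(tid1) >= min_supp_x]

  # levelwise growth restricted to frequent singletons
  freq_bodies <- list()
  for (tok in names(tid1)) {
    freq_bodies[[tok]] <- tid1[[tok]]
  }
  if (max_body >= 2L && length(tid1) >= 2L) {
    level <- lapply(names(tid1), function(t) t)
    names(level) <- names(tid1)
    level_tids <- tid1
    for (size in 2:max_body) {
      keys <- names(level_tids)
      next_level <- list()
      next_tids <- list()
      if (length(keys) >= 2L) {
        for (i in seq_len(length(keys) - 1L)) {
          for (j in seq((i + 1L), length(keys))) {
            a <- level[[keys[i]]]
            b <- level[[keys[j]]]
            items <- sort(unique(c(a, b)))
            if (length(items) != size) next
            key <- paste(items, collapse = ";")
            if (!is.null(next_tids[[key]])) next
            tids <- intersect(level_tids[[keys[i]]], level_tids[[keys[j]]])
            if (length(tids) < min_supp_x) next
            next_level[[key]] <- items
            next_tids[[key]] <- tids
          }
        }
      }
      for (key in names(next_tids)) freq_bodies[[key]] <- next_tids[[key]]
      if (length(next_tids) < 2L || size == max_body) break
      level <- next_level
      level_tids <- next_tids
    }
  }
  if (length(freq_bodies) == 0L) return(.empty_rules(origin))

  # head tid lists
  sub_list <- lapply(txns, `[[`, "substructures")
  head_tids <- split(rep(seq_len(n), lengths(sub_list)),
                     unlist(sub_list, use.names = FALSE))
  head_tids <- head_tids[lengths(head_tids) >= min_tp]
  if (length(head_tids) == 0L) return(.empty_rules(origin))

  rows <- vector("list", length(freq_bodies) * length(head_tids))
  ri <- 0L
  for (bkey in names(freq_bodies)) {
    btids <- freq_bodies[[bkey]]
    for (hkey in names(head_tids)) {
      tp <- length(intersect(btids, head_tids[[hkey]]))
      if (tp < min_tp) next
      ri <- ri + 1L
      rows[[ri]] <- data.frame(
        body = .body_key(strsplit(bkey, ";", fixed = TRUE)[[1L]]),
        head = hkey,
        supp_x = length(btids),
        supp_y = length(head_tids[[hkey]]),
        tp = tp,
        stringsAsFactors = FALSE
      )
    }
  }
  if (ri == 0L) return(.empty_rules(origin))
  df <- do.call(rbind, rows[seq_len(ri)])
  df$precision <- df$tp / df$supp_x
  df$recall <- df$tp / df$supp_y
  body_size <- lengths(strsplit(df$body, ";", fixed = TRUE))
  ord <- order(-df$recall, -df$precision, body_size, df$head, df$body)
  df <- df[ord, , drop = FALSE]
  df <- cbind(rule_id = seq_len(nrow(df)), origin = origin, df)
  rownames(df) <- NULL
  class(df) <- c("ms2_rules", "data.frame")
  df
}

.empty_rules <- function(origin) {
  df <- data.frame(
    rule_id = integer(0L), origin = character(0L), body = character(0L),
    head = character(0L), supp_x = integer(0L), supp_y = integer(0L),
    tp = integer(0L), precision = numeric(0L), recall = numeric(0L),
    stringsAsFactors = FALSE
  )
  class(df) <- c("ms2_rules", "data.frame")
  df
}

#' Re-evaluate rules on an independent transaction set
#'
#' Recomputes the confusion matrix of each rule by exact counting over
#' `txns` (typically built from an independent test library): `supp_x`
#' spectra contain the body, `supp_y` compounds contain the head, `tp`
#' both. Rules with fewer than `min_tp` test true positives are flagged
#' not evaluable (their precision/recall estimates would rest on too few
#' occurrences); precision is `NA` when the body never occurs.
#'
#' @param rules An `ms2_rules` data frame.
#' @param txns Transactions from [build_transactions()].
#' @param min_tp Evaluability cutoff on the test true-positive count.
#' @return Data frame with columns `rule_id`, `body`, `head`, `supp_x`,
#'   `supp_y`, `tp`, `fp`, `fn`, `tn`, `precision`, `recall`, `evaluable`.
#' @export
evaluate_rules <- function(rules, txns, min_tp = 5L) {
  stopifnot(inherits(rules, "ms2_rules") || is.data.frame(rules))
  n <- length(txns)
  feat_tokens <- lapply(txns, function(tx) unique(feature_key(tx$features)))
  sub_list <- lapply(txns, `[[`, "substructures")

  res <- lapply(seq_len(nrow(rules)), function(i) {
    body_toks <- strsplit(rules$body[i], ";", fixed = TRUE)[[1L]]
    in_x <- vapply(feat_tokens, function(tk) all(body_toks %in% tk), logical(1L))
    in_y <- vapply(sub_list, function(s) rules$head[i] %in% s, logical(1L))
    tp <- sum(in_x & in_y)
    data.frame(
      rule_id = rules$rule_id[i], body = rules$body[i], head = rules$head[i],
      supp_x = sum(in_x), supp_y = sum(in_y), tp = tp,
      fp = sum(in_x & !in_y), fn = sum(!in_x & in_y),
      tn = sum(!in_x & !in_y),
      precision = if (sum(in_x) > 0L) tp / sum(in_x) else NA_real_,
      recall = if (sum(in_y) > 0L) tp / sum(in_y) else NA_real_,
      evaluable = tp >= min_tp,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Write a rule database as TSV
#'
#' Header comment lines carry the configuration fingerprint so that rule
#' databases mined under different settings are never silently combined.
#'
#' @param rules An `ms2_rules` data frame.
#' @param path Output path.
#' @param config A [pipeline_config()] (serialized into the header).
#' @return `path`, invisibly.
#' @export
write_rule_db <- function(rules, path, config = pipeline_config()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# config: ", config_fingerprint(config)), con)
  utils::write.table(as.data.frame(rules), con, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a rule database TSV
#'
#' @param path Path written by [write_rule_db()].
#' @return An `ms2_rules` data frame with attribute `"config_fingerprint"`.
#' @export
read_rule_db <- function(path) {
  lines <- readLines(path, n = 10L)
  fp <- sub("^# config: ", "", grep("^# config: ", lines, value = TRUE))
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  class(df) <- c("ms2_rules", "data.frame")
  attr(df, "config_fingerprint") <- if (length(fp) > 0L) fp[1L] else NA_character_
  df
}
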