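# Independent brute-force oracles and small fixture builders shared by the
# tests. These re-derive expected behavior from first principles and stay
# independent of the implementation paths they check.

# -- leftmost-longest dictionary labeling, straight off the lexicon table --
# case policy: terms of >= 4 characters match case-insensitively.
oracle_priority <- function(cls) {
  ranks <- c(CellLineSymbol = 1, CellTypeSymbol = 1, ChromosomeSymbol = 1,
             GeneSymbol = 1,
             CellKeyword = 2, CellLineKeyword = 2, DNAKeyword = 2,
             ProteinKeyword = 2, RNAKeyword = 2, Enzyme = 2,
             BiologicalProcess = 3, Chemical = 3, Disease = 3,
             Morphology = 3, OrganTissue = 3, Taxonomy = 3, Structure = 3,
             Unit = 3,
             Conjunction = 4, Preposition = 4, Specifier = 4)
  unname(ranks[cls])
}

oracle_lex_classes <- function(lex, phrase) {
  hit <- (lex$term == phrase) |
    (nchar(lex$term) >= 4 & tolower(lex$term) == tolower(phrase))
  unique(lex$class[hit])
}

oracle_label <- function(lex, surfaces, regexes = character(0)) {
  n <- length(surfaces)
  max_len <- if (nrow(lex) > 0) {
    max(vapply(strsplit(lex$term, " +"), length, 0L))
  } else 0L
  out <- NULL
  i <- 1L
  while (i <= n) {
    placed <- FALSE
    for (len in rev(seq_len(min(max_len, n - i + 1L)))) {
      phrase <- paste(surfaces[i:(i + len - 1L)], collapse = " ")
      cls <- oracle_lex_classes(lex, phrase)
      if (length(cls) > 0L) {
        cls <- cls[order(oracle_priority(cls), cls)][1L]
        out <- rbind(out, data.frame(concept = cls, token_start = i,
                                     token_end = i + len,
                                     matched_term = phrase,
                                     stringsAsFactors = FALSE))
        i <- i + len
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      for (k in seq_along(regexes)) {
        if (grepl(regexes[[k]], surfaces[i])) {
          out <- rbind(out, data.frame(concept = names(regexes)[k],
                                       token_start = i, token_end = i + 1L,
                                       matched_term = surfaces[i],
                                       stringsAsFactors = FALSE))
          placed <- TRUE
          break
        }
      }
      i <- i + 1L
    }
  }
  if (is.null(out)) {
    out <- data.frame(concept = character(0), token_start = integer(0),
                      token_end = integer(0), matched_term = character(0),
                      stringsAsFactors = FALSE)
  }
  out
}

# -- brute-force pattern-alignment enumeration ------------------------------
# A legal alignment picks an increasing sequence of labels whose concepts
# spell a subsequence of the pattern that keeps the first and last concepts,
# deletes at most floor((len-1)/2) interior concepts, and leaves gaps of at
# most `max_ins` tokens between consecutive matched labels (all gap tokens
# inserted). Returns one row per legal alignment with its span and op
# counts.
oracle_alignments <- function(concepts, labels, max_ins = 2L,
                              max_del_cap = NULL) {
  plen <- length(concepts)
  max_del <- floor((plen - 1) / 2)
  if (!is.null(max_del_cap)) max_del <- min(max_del, max_del_cap)
  interior <- setdiff(seq_len(plen), c(1L, plen))
  del_subsets <- list()
  for (mask in 0:(2^length(interior) - 1L)) {
    del <- interior[bitwAnd(mask, 2^(seq_along(interior) - 1L)) > 0L]
    if (length(del) <= max_del) del_subsets[[length(del_subsets) + 1L]] <- del
  }
  out <- NULL
  nl <- nrow(labels)
  for (del in del_subsets) {
    kept <- setdiff(seq_len(plen), del)
    want <- concepts[kept]
    k <- length(want)
    # all increasing label index sequences of length k matching `want`
    seqs <- list(integer(0))
    for (j in seq_len(k)) {
      nxt <- list()
      for (s in seqs) {
        lo <- if (length(s) == 0L) 1L else s[length(s)] + 1L
        for (li in seq(lo, nl)) {
          if (lo > nl) break
          if (labels$concept[li] == want[j]) nxt[[length(nxt) + 1L]] <- c(s, li)
        }
      }
      seqs <- nxt
      if (length(seqs) == 0L) break
    }
    for (s in seqs) {
      ok <- TRUE
      n_ins <- 0L
      if (k > 1L) {
        for (j in seq_len(k - 1L)) {
          gap <- labels$token_start[s[j + 1L]] - labels$token_end[s[j]]
          if (gap < 0L || gap > max_ins) { ok <- FALSE; break }
          n_ins <- n_ins + gap
        }
      }
      if (!ok) next
      sig <- paste(sprintf("%s:%d-%d", want, labels$token_start[s],
                           labels$token_end[s]), collapse = ",")
      out <- rbind(out, data.frame(
        tok_start = labels$token_start[s[1L]],
        tok_end = labels$token_end[s[k]],
        n_matched = k, n_inserted = n_ins, n_deleted = length(del),
        match_sig = sig, stringsAsFactors = FALSE))
    }
  }
  if (is.null(out)) {
    out <- data.frame(tok_start = integer(0), tok_end = integer(0),
                      n_matched = integer(0), n_inserted = integer(0),
                      n_deleted = integer(0), match_sig = character(0),
                      stringsAsFactors = FALSE)
  }
  unique(out)
}

match_signature <- function(m) {
  al <- m$alignment[m$alignment$op == "MATCH", , drop = FALSE]
  paste(sprintf("%s:%d-%d", al$concept, al$token_start, al$token_end),
        collapse = ",")
}

# -- optimal one-to-one mention matching (exhaustive) -----------------------
oracle_best_tp <- function(gold, pred, mode) {
  ok_pair <- function(gi, pj) {
    if (gold$doc_id[gi] != pred$doc_id[pj] ||
        gold$section[gi] != pred$section[pj]) return(FALSE)
    if (mode == "strict") {
      gold$start[gi] == pred$start[pj] && gold$end[gi] == pred$end[pj]
    } else {
      pred$start[pj] < gold$end[gi] && pred$end[pj] > gold$start[gi]
    }
  }
  recurse <- function(gi, used) {
    if (gi > nrow(gold)) return(0L)
    best <- recurse(gi + 1L, used)   # leave this gold unmatched
    for (pj in seq_len(nrow(pred))) {
      if (!used[pj] && ok_pair(gi, pj)) {
        u <- used; u[pj] <- TRUE
        best <- max(best, 1L + recurse(gi + 1L, u))
      }
    }
    best
  }
  if (nrow(gold) == 0L) return(0L)
  recurse(1L, rep(FALSE, max(nrow(pred), 1L)))
}

# -- random mention layouts -------------------------------------------------
random_layout <- function(doc_id = "d1", n_tokens = 12L, n_ments = 2L,
                          types = c("GPRO_TYPE_1", "GPRO_TYPE_2")) {
  words <- replicate(n_tokens, paste(sample(letters, 4L, TRUE), collapse = ""))
  text <- paste(words, collapse = " ")
  toks <- tokenize(text, tagger = identity_tagger)
  rows <- NULL
  free <- rep(TRUE, n_tokens)
  made <- 0L
  while (made < n_ments && any(free)) {
    len <- sample(1:3, 1L)
    starts <- which(vapply(seq_len(n_tokens - len + 1L),
                           function(s) all(free[s:(s + len - 1L)]), TRUE))
    if (length(starts) == 0L) break
    s <- if (length(starts) == 1L) starts else sample(starts, 1L)
    free[s:(s + len - 1L)] <- FALSE
    rows <- rbind(rows, data.frame(
      start = toks$start[s], end = toks$end[s + len - 1L],
      etype = sample(types, 1L), stringsAsFactors = FALSE))
    made <- made + 1L
  }
  ments <- if (is.null(rows)) mentions() else {
    rows <- rows[order(rows$start), , drop = FALSE]
    mentions(doc_id, "abstract", rows$start, rows$end,
             slice_text(text, rows$start, rows$end), rows$etype)
  }
  list(text = text, tokens = toks, mentions = ments)
}

subset_corpus <- function(df, ids) {
  out <- df[df$doc_id %in% ids, , drop = FALSE]
  class(out) <- class(df)
  out
}

# gold/pred pair with jittered predictions for metric properties
random_eval_pair <- function(seed_offset) {
  lay <- random_layout(doc_id = sprintf("d%d", seed_offset %% 3L),
                       n_tokens = sample(8:14, 1L), n_ments = sample(0:4, 1L))
  gold <- lay$mentions
  # predictions: jittered copies of gold plus occasional noise, kept
  # non-overlapping
  toks <- lay$tokens
  rows <- NULL
  for (i in seq_len(nrow(gold))) {
    if (runif(1) < 0.2) next                    # missed
    s <- gold$start[i]; e <- gold$end[i]
    if (runif(1) < 0.4) {                       # boundary jitter within span
      if (e - s > 2L && runif(1) < 0.5) s <- s + 1L else e <- e - 1L
    }
    if (s < e) rows <- rbind(rows, data.frame(start = s, end = e))
  }
  pred <- if (is.null(rows)) mentions() else {
    rows <- rows[order(rows$start), , drop = FALSE]
    keep <- rep(TRUE, nrow(rows))
    last_end <- -1L
    for (i in seq_len(nrow(rows))) {
      if (rows$start[i] < last_end) keep[i] <- FALSE
      else last_end <- rows$end[i]
    }
    rows <- rows[keep, , drop = FALSE]
    mentions(gold$doc_id[1], "abstract", rows$start, rows$end,
             substring(lay$text, rows$start + 1L, rows$end),
             sample(c("GPRO_TYPE_1", "GPRO_TYPE_2"), nrow(rows), TRUE))
  }
  list(gold = gold, pred = pred)
}
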