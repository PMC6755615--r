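# Statistical principle-based approach: induce concept patterns from gold
# mentions, match them against CKB-labeled sentences allowing word
# insertions and concept deletions, and score matches with a tuned
# logistic model.

#' Matching limits for approximate pattern matching
#'
#' An alignment may insert at most `max_insert_run` consecutive sentence
#' tokens between adjacent matched concepts and delete at most
#' `floor((length - 1) / 2)` pattern concepts (capped by `max_delete` when
#' given); the first and last pattern concepts must match, so insertions
#' never hang off a span boundary.
#'
#' @param max_insert_run maximum consecutive inserted tokens.
#' @param max_delete optional absolute cap on deleted concepts.
#' @return A list of class `spba_limits`.
#' @export
spba_limits <- function(max_insert_run = 2L, max_delete = NULL) {
  structure(list(max_insert_run = as.integer(max_insert_run),
                 max_delete = max_delete), class = "spba_limits")
}

pattern_key <- function(concepts) paste(concepts, collapse = "|")

#' Induce a concept pattern from one gold mention
#'
#' All non-overlapping CKB labelings of the mention tokens are enumerated;
#' the labeling covering the most words (highest labeled ratio) is kept,
#' unlabeled words are dropped, and the remaining concept-class sequence is
#' the pattern. Ratio ties are broken by the fixed class priority.
#'
#' @param mention_tokens `gpro_tokens` for one mention.
#' @param ckb a `ckb` object.
#' @return `NULL` when no token is labeled, otherwise a list with
#'   `concepts` (character vector), `source_mention` and `labeled_ratio`.
#' @export
generate_pattern <- function(mention_tokens, ckb) {
  n <- nrow(mention_tokens)
  if (n == 0L) return(NULL)
  labelings <- enumerate_labelings(ckb, mention_tokens)
  covered <- vapply(labelings, function(lab) {
    if (nrow(lab) == 0L) 0L else sum(lab$token_end - lab$token_start)
  }, 0L)
  if (max(covered) == 0L) return(NULL)
  best <- labelings[covered == max(covered)]
  if (length(best) > 1L) {
    # deterministic tie-break: element-wise class priority, then name
    keys <- vapply(best, function(lab) {
      paste(sprintf("%d%s", class_priority(lab$concept), lab$concept),
            collapse = " ")
    }, "")
    best <- best[order(keys)]
  }
  lab <- best[[1L]]
  lab <- lab[order(lab$token_start), , drop = FALSE]
  list(concepts = lab$concept,
       source_mention = paste(mention_tokens$surface, collapse = " "),
       labeled_ratio = max(covered) / n)
}

#' Induce the deduplicated pattern set from gold mentions
#'
#' Mentions with identical concept sequences collapse to one pattern with an
#' occurrence count; output order is by count (descending) then
#' lexicographic on the concept sequence, so runs are reproducible.
#'
#' @param gold a `gpro_mentions` data frame.
#' @param ckb a `ckb` object.
#' @param tagger tokenizer tagger for the mention texts.
#' @return List of patterns (each with `concepts`, `source_mention`,
#'   `labeled_ratio`, `count`).
#' @export
generate_pattern_set <- function(gold, ckb, tagger = regex_tagger) {
  pats <- list()
  counts <- integer(0)
  if (nrow(gold) > 0L) {
    for (i in seq_len(nrow(gold))) {
      toks <- tokenize(gold$text[i], tagger = tagger)
      p <- generate_pattern(toks, ckb)
      if (is.null(p)) next
      k <- pattern_key(p$concepts)
      if (is.na(counts[k])) {
        pats[[k]] <- p
        counts[k] <- 1L
      } else {
        counts[k] <- counts[k] + 1L
        if (p$labeled_ratio > pats[[k]]$labeled_ratio) pats[[k]] <- p
      }
    }
  }
  if (length(pats) == 0L) return(list())
  ord <- order(-counts, names(counts))
  out <- lapply(names(counts)[ord], function(k) {
    p <- pats[[k]]
    p$count <- unname(counts[k])
    p
  })
  out
}

#' Serialize patterns to JSON
#' @param patterns list of patterns from [generate_pattern_set()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_patterns <- function(patterns, path) {
  jsonlite::write_json(
    lapply(patterns, function(p) {
      list(concepts = p$concepts, source = p$source_mention,
           labeled_ratio = p$labeled_ratio,
           count = if (is.null(p$count)) 1L else p$count)
    }),
    path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' Read patterns from JSON
#' @param path patterns file written by [write_patterns()].
#' @return List of patterns.
#' @export
read_patterns <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  lapply(raw, function(p) {
    list(concepts = unlist(p$concepts), source_mention = unlist(p$source),
         labeled_ratio = unlist(p$labeled_ratio), count = unlist(p$count))
  })
}

#' Match a pattern against a labeled sentence
#'
#' Alignment semantics: the first pattern concept must MATCH a concept label
#' of the same class; subsequent concepts may MATCH, or be DELETEd (never
#' the first or last concept, at most `floor((len-1)/2)` overall), and
#' between matches up to `max_insert_run` consecutive sentence tokens may be
#' INSERTed. The span runs from the first to the last matched label; all
#' alignments within limits are enumerated and, per span, only the
#' highest-scoring alignment is kept.
#'
#' @param pattern a pattern list (`concepts`, ...).
#' @param labels concept labels from [label_sentence()].
#' @param tokens the sentence tokens the labels refer to.
#' @param limits an [spba_limits()] object.
#' @param weights optional `WeightVector` (list with `weights`, `bias`) used
#'   to score alignments; zero weights when omitted.
#' @return List of match results: `tok_start`, `tok_end` (1-based,
#'   half-open), `alignment` (data frame of ops), `features`, `score`.
#' @export
match_pattern <- function(pattern, labels, tokens, limits = spba_limits(),
                          weights = NULL) {
  concepts <- pattern$concepts
  plen <- length(concepts)
  if (plen == 0L || nrow(labels) == 0L) return(list())
  max_del <- floor((plen - 1L) / 2L)
  if (!is.null(limits$max_delete)) max_del <- min(max_del, limits$max_delete)
  max_ins <- limits$max_insert_run
  lab_start <- labels$token_start
  results <- list()

  emit <- function(ops) {
    al <- do.call(rbind, ops)
    m <- al[al$op == "MATCH", , drop = FALSE]
    results[[length(results) + 1L]] <<- list(
      tok_start = min(m$token_start), tok_end = max(m$token_end),
      alignment = al)
  }

  # walk(pi, tpos, ins_run, dels, ops): try to align pattern concepts
  # pi..plen starting at sentence token position tpos
  walk <- function(pi, tpos, ins_run, dels, ops) {
    if (pi > plen) { emit(ops); return(invisible()) }
    # MATCH a label starting exactly at tpos
    li <- which(lab_start == tpos)
    if (length(li) == 1L && labels$concept[li] == concepts[pi]) {
      walk(pi + 1L, labels$token_end[li], 0L, dels,
           c(ops, list(data.frame(op = "MATCH", concept = concepts[pi],
                                  token_start = tpos,
                                  token_end = labels$token_end[li],
                                  stringsAsFactors = FALSE))))
    }
    # DELETE concept pi (interior concepts only)
    if (pi > 1L && pi < plen && dels < max_del) {
      walk(pi + 1L, tpos, ins_run, dels + 1L,
           c(ops, list(data.frame(op = "DELETE", concept = concepts[pi],
                                  token_start = NA_integer_,
                                  token_end = NA_integer_,
                                  stringsAsFactors = FALSE))))
    }
    # INSERT sentence token tpos (only strictly inside the span)
    if (pi > 1L && ins_run < max_ins && tpos <= nrow(tokens)) {
      walk(pi, tpos + 1L, ins_run + 1L, dels,
           c(ops, list(data.frame(op = "INSERT", concept = NA_character_,
                                  token_start = tpos, token_end = tpos + 1L,
                                  stringsAsFactors = FALSE))))
    }
  }

  for (s in which(labels$concept == concepts[1L])) {
    walk(2L, labels$token_end[s], 0L, 0L,
         list(data.frame(op = "MATCH", concept = concepts[1L],
                         token_start = labels$token_start[s],
                         token_end = labels$token_end[s],
                         stringsAsFactors = FALSE)))
  }
  if (length(results) == 0L) return(list())

  results <- lapply(results, function(r) {
    r$pattern <- pattern
    r$features <- featurize_match(r, tokens)
    r$score <- score_match(r$features, weights)
    r
  })
  # per span keep the best-scoring alignment (ties: fewer inserts, deletes)
  key <- vapply(results, function(r) sprintf("%d:%d", r$tok_start, r$tok_end), "")
  keep <- list()
  for (k in unique(key)) {
    grp <- results[key == k]
    sc <- vapply(grp, function(r) r$score, 0)
    ni <- vapply(grp, function(r) sum(r$alignment$op == "INSERT"), 0L)
    nd <- vapply(grp, function(r) sum(r$alignment$op == "DELETE"), 0L)
    keep[[length(keep) + 1L]] <- grp[[order(-sc, ni, nd)[1L]]]
  }
  keep
}

GREEK_WORDS <- c("alpha", "beta", "gamma", "delta", "epsilon", "zeta",
                 "eta", "theta", "kappa", "lambda", "mu", "sigma", "omega")

#' Feature vector for one pattern-match result
#'
#' Alignment features (matched/inserted/deleted counts and per-concept match
#' indicators), context features (word and POS identity one token left and
#' right of the span), and morphology flags over the span tokens
#' (capitalization, digits, hyphen, Greek-letter word).
#'
#' @param m a match result from [match_pattern()] (before scoring).
#' @param tokens the sentence tokens.
#' @return A named numeric vector.
#' @export
featurize_match <- function(m, tokens) {
  al <- m$alignment
  f <- c(n_matched = sum(al$op == "MATCH"),
         n_inserted = sum(al$op == "INSERT"),
         n_deleted = sum(al$op == "DELETE"))
  for (cc in unique(al$concept[al$op == "MATCH"])) {
    f[paste0("match=", cc)] <- sum(al$op == "MATCH" & al$concept == cc)
  }
  n <- nrow(tokens)
  lt <- if (m$tok_start > 1L) tokens$surface[m$tok_start - 1L] else "<BOS>"
  lp <- if (m$tok_start > 1L) tokens$pos[m$tok_start - 1L] else "<BOS>"
  rt <- if (m$tok_end <= n) tokens$surface[m$tok_end] else "<EOS>"
  rp <- if (m$tok_end <= n) tokens$pos[m$tok_end] else "<EOS>"
  f[paste0("wl=", tolower(lt))] <- 1
  f[paste0("posl=", lp)] <- 1
  f[paste0("wr=", tolower(rt))] <- 1
  f[paste0("posr=", rp)] <- 1
  span <- tokens$surface[m$tok_start:(m$tok_end - 1L)]
  f["m_init_cap"] <- as.numeric(any(grepl("^[A-Z]", span)))
  f["m_all_caps"] <- as.numeric(any(grepl("^[A-Z]{2,}$", span)))
  f["m_has_digit"] <- as.numeric(any(grepl("[0-9]", span)))
  f["m_has_hyphen"] <- as.numeric(any(grepl("-", span, fixed = TRUE)))
  f["m_greek"] <- as.numeric(any(tolower(span) %in% GREEK_WORDS))
  f
}

#' Logistic score of a feature vector
#'
#' @param features named numeric vector.
#' @param w `WeightVector`: list with named numeric `weights` and scalar
#'   `bias`; feature names without a weight contribute 0. `NULL` means all
#'   zero weights (score 0.5).
#' @return Probability in (0, 1).
#' @export
score_match <- function(features, w = NULL) {
  if (is.null(w)) return(0.5)
  wt <- w$weights[names(features)]
  wt[is.na(wt)] <- 0
  plogis(sum(wt * features) + w$bias)
}

#' Tune match-scoring weights by regularized logistic regression
#'
#' Fits an L2-penalized (ridge) logistic regression of candidate labels on
#' match features, minimizing the penalized log loss; the fit is
#' deterministic for fixed inputs and `lambda`.
#'
#' @param candidates list of `list(features = named numeric, label = logical)`.
#' @param lambda ridge penalty passed to glmnet (default `1e-3`).
#' @return A `WeightVector`: `list(weights, bias)`.
#' @export
tune_weights <- function(candidates, lambda = 1e-3) {
  labs <- vapply(candidates, function(cnd) isTRUE(cnd$label), TRUE)
  if (length(unique(labs)) < 2L) {
    stop("degenerate data: need at least one positive and one negative candidate")
  }
  feat_names <- sort(unique(unlist(lapply(candidates, function(cnd) names(cnd$features)))))
  x <- matrix(0, nrow = length(candidates), ncol = length(feat_names),
              dimnames = list(NULL, feat_names))
  for (i in seq_along(candidates)) {
    fv <- candidates[[i]]$features
    x[i, names(fv)] <- fv
  }
  if (ncol(x) < 2L) {
    # glmnet needs >= 2 columns; pad with a void column
    x <- cbind(x, `.pad.` = 0)
  }
  fit <- glmnet::glmnet(x, as.numeric(labs), family = "binomial", alpha = 0,
                        lambda = lambda, standardize = FALSE, thresh = 1e-10,
                        maxit = 1e6)
  beta <- as.numeric(fit$beta)
  names(beta) <- rownames(fit$beta)
  beta <- beta[names(beta) != ".pad."]
  list(weights = beta, bias = as.numeric(fit$a0))
}

#' Serialize / read a weight vector as JSON
#' @param w a `WeightVector`.
#' @param path file path.
#' @return `path` (write) or the `WeightVector` (read).
#' @export
write_weights <- function(w, path) {
  jsonlite::write_json(list(weights = as.list(w$weights), bias = w$bias),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_weights
#' @export
read_weights <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  list(weights = unlist(raw$weights), bias = as.numeric(raw$bias))
}

#' Predict gene mentions in one sentence with SPBA
#'
#' Runs every pattern over the labeled sentence, keeps matches scoring at
#' least `threshold`, and resolves overlaps by score, then span length, then
#' leftmost position. Matches are emitted as `GENE` mentions with character
#' offsets.
#'
#' @param patterns list of patterns.
#' @param w `WeightVector` for scoring.
#' @param tokens sentence tokens (offsets relative to the section).
#' @param labels CKB labels for `tokens` (computed when omitted).
#' @param ckb `ckb` object, required when `labels` is missing.
#' @param doc_id,section identity of the sentence's document section.
#' @param text the full section text (for mention text slices).
#' @param threshold decision threshold on the logistic score.
#' @param limits [spba_limits()].
#' @return A `gpro_mentions` data frame with `etype = "GENE"`.
#' @export
predict_gene_mentions <- function(patterns, w, tokens, labels = NULL,
                                  ckb = NULL, doc_id = "doc",
                                  section = "abstract", text = NULL,
                                  threshold = 0.5, limits = spba_limits()) {
  if (is.null(labels)) {
    stopifnot(!is.null(ckb))
    labels <- label_sentence(ckb, tokens)
  }
  all_matches <- list()
  for (p in patterns) {
    ms <- match_pattern(p, labels, tokens, limits, weights = w)
    all_matches <- c(all_matches, ms)
  }
  all_matches <- Filter(function(m) m$score >= threshold, all_matches)
  if (length(all_matches) == 0L) return(mentions())
  sc <- vapply(all_matches, function(m) m$score, 0)
  len <- vapply(all_matches, function(m) m$tok_end - m$tok_start, 0L)
  st <- vapply(all_matches, function(m) m$tok_start, 0L)
  ord <- order(-sc, -len, st)
  taken <- rep(FALSE, nrow(tokens))
  kept <- list()
  for (i in ord) {
    m <- all_matches[[i]]
    idx <- m$tok_start:(m$tok_end - 1L)
    if (any(taken[idx])) next
    taken[idx] <- TRUE
    kept[[length(kept) + 1L]] <- m
  }
  kept <- kept[order(vapply(kept, function(m) m$tok_start, 0L))]
  cs <- vapply(kept, function(m) tokens$start[m$tok_start], 0L)
  ce <- vapply(kept, function(m) tokens$end[m$tok_end - 1L], 0L)
  txt <- if (!is.null(text)) slice_text(text, cs, ce) else
    vapply(kept, function(m) paste(tokens$surface[m$tok_start:(m$tok_end - 1L)],
                                   collapse = " "), "")
  mentions(doc_id, section, cs, ce, txt, "GENE")
}
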