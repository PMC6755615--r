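# End-to-end glue: sentence preparation, SPBA training and prediction over
# a corpus, and the combined SPBA-CRF GPRO recognizer.

# one section of one document, split into sentences of word tokens with
# section-relative character offsets
section_sentences <- function(text, tagger = regex_tagger) {
  spans <- split_sentences(text)
  out <- vector("list", nrow(spans))
  for (i in seq_len(nrow(spans))) {
    toks <- tokenize(slice_text(text, spans$start[i], spans$end[i]), tagger)
    if (nrow(toks) > 0L) {
      toks$start <- toks$start + spans$start[i]
      toks$end <- toks$end + spans$start[i]
    }
    out[[i]] <- toks
  }
  out[vapply(out, nrow, 0L) > 0L]
}

for_each_sentence <- function(corp, tagger, fn) {
  for (d in seq_len(nrow(corp))) {
    for (sec in SECTIONS) {
      txt <- section_text(corp, corp$doc_id[d], sec)
      if (!nzchar(txt)) next
      for (toks in section_sentences(txt, tagger)) {
        fn(corp$doc_id[d], sec, txt, toks)
      }
    }
  }
}

#' Train the SPBA gene-mention recognizer
#'
#' Induces patterns from the gold mentions (types are collapsed: SPBA
#' recognizes generic gene mentions), generates match candidates over the
#' training corpus, labels each candidate by whether its span exactly
#' equals a gold span, and tunes the logistic scoring weights.
#'
#' @param corp training corpus.
#' @param gold gold mentions (any etype; treated uniformly).
#' @param ckb a `ckb` object.
#' @param limits [spba_limits()].
#' @param lambda ridge penalty for [tune_weights()].
#' @param threshold decision threshold stored with the model.
#' @param tagger POS/chunk tagger.
#' @return An `spba_model` list: `patterns`, `weights`, `threshold`,
#'   `limits`.
#' @export
spba_train <- function(corp, gold, ckb, limits = spba_limits(),
                       lambda = 1e-3, threshold = 0.5,
                       tagger = regex_tagger) {
  validate_mentions(gold, corp)
  patterns <- generate_pattern_set(gold, ckb, tagger)
  if (length(patterns) == 0L) stop("no patterns could be induced from the gold mentions")
  candidates <- list()
  for_each_sentence(corp, tagger, function(doc_id, sec, txt, toks) {
    labels <- label_sentence(ckb, toks)
    if (nrow(labels) == 0L) return(invisible())
    gsec <- gold[gold$doc_id == doc_id & gold$section == sec, , drop = FALSE]
    for (p in patterns) {
      for (m in match_pattern(p, labels, toks, limits)) {
        cs <- toks$start[m$tok_start]
        ce <- toks$end[m$tok_end - 1L]
        is_gold <- any(gsec$start == cs & gsec$end == ce)
        candidates[[length(candidates) + 1L]] <<-
          list(features = m$features, label = is_gold)
      }
    }
  })
  if (length(candidates) == 0L) stop("no match candidates found on the training corpus")
  w <- tune_weights(candidates, lambda = lambda)
  structure(list(patterns = patterns, weights = w, threshold = threshold,
                 limits = limits, n_candidates = length(candidates)),
            class = "spba_model")
}

#' @export
print.spba_model <- function(x, ...) {
  cat(sprintf("<spba_model> %d patterns, %d scoring weights, threshold %.2f\n",
              length(x$patterns), length(x$weights$weights), x$threshold))
  invisible(x)
}

#' Predict SPBA gene mentions over a corpus
#'
#' @param model an `spba_model`.
#' @param corp a `gpro_corpus`.
#' @param ckb the `ckb` used for labeling.
#' @param tagger POS/chunk tagger.
#' @return A `gpro_mentions` data frame with `etype = "GENE"`.
#' @export
spba_predict <- function(model, corp, ckb, tagger = regex_tagger) {
  out <- list()
  for_each_sentence(corp, tagger, function(doc_id, sec, txt, toks) {
    labels <- label_sentence(ckb, toks)
    if (nrow(labels) == 0L) return(invisible())
    m <- predict_gene_mentions(model$patterns, model$weights, toks,
                               labels = labels, doc_id = doc_id,
                               section = sec, text = txt,
                               threshold = model$threshold,
                               limits = model$limits)
    if (nrow(m) > 0L) out[[length(out) + 1L]] <<- m
  })
  if (length(out) == 0L) return(mentions())
  res <- do.call(rbind, out)
  class(res) <- c("gpro_mentions", "data.frame")
  validate_mentions(res, corp)
  res
}

featurize_corpus <- function(corp, spba_ments, use_spba, tagger) {
  feats <- list(); labs <- list(); meta <- list()
  for_each_sentence(corp, tagger, function(doc_id, sec, txt, toks) {
    st <- sub_tokenize_all(toks)
    sm <- if (!is.null(spba_ments)) {
      spba_ments[spba_ments$doc_id == doc_id & spba_ments$section == sec, ,
                 drop = FALSE]
    } else NULL
    feats[[length(feats) + 1L]] <<- extract_features(st, sm, use_spba)
    meta[[length(meta) + 1L]] <<- list(doc_id = doc_id, section = sec,
                                       text = txt, tokens = st)
  })
  list(feats = feats, meta = meta)
}

#' Train the full GPRO recognizer (SPBA + CRF)
#'
#' Trains SPBA on the training gold (unless an existing `spba_model` is
#' supplied or `use_spba = FALSE`), predicts SPBA gene mentions over the
#' training corpus, and trains the SOBIE CRF on sub-token features with the
#' SPBA predictions as an extra feature group.
#'
#' @param corp training corpus.
#' @param gold gold `GPRO_TYPE_1`/`GPRO_TYPE_2` mentions.
#' @param ckb a `ckb` object.
#' @param use_spba include the SPBA feature group.
#' @param spba_model optional pre-trained `spba_model`.
#' @param l2,maxit CRF hyperparameters, see [train_crf()].
#' @param tagger POS/chunk tagger.
#' @param ... passed to [spba_train()].
#' @return A `gpro_model` list.
#' @export
gpro_train <- function(corp, gold, ckb, use_spba = TRUE, spba_model = NULL,
                       l2 = 0.1, maxit = 150L, tagger = regex_tagger, ...) {
  validate_mentions(gold, corp)
  if (use_spba && is.null(spba_model)) {
    spba_model <- spba_train(corp, gold, ckb, tagger = tagger, ...)
  }
  spba_ments <- if (use_spba) spba_predict(spba_model, corp, ckb, tagger) else NULL
  fc <- featurize_corpus(corp, spba_ments, use_spba, tagger)
  labs <- lapply(fc$meta, function(m) {
    gsec <- gold[gold$doc_id == m$doc_id & gold$section == m$section, ,
                 drop = FALSE]
    encode_sobie(m$tokens, gsec)
  })
  crf <- train_crf(fc$feats, labs, l2 = l2, maxit = maxit)
  structure(list(crf = crf, spba = spba_model, use_spba = use_spba,
                 ckb = ckb), class = "gpro_model")
}

#' @export
print.gpro_model <- function(x, ...) {
  cat(sprintf("<gpro_model> CRF with %d features; SPBA features %s\n",
              x$crf$nfeat, if (x$use_spba) "on" else "off"))
  invisible(x)
}

#' Predict GPRO mentions over a corpus
#'
#' @param model a `gpro_model`.
#' @param corp a `gpro_corpus`.
#' @param tagger POS/chunk tagger (must match training).
#' @return A `gpro_mentions` data frame of `GPRO_TYPE_1`/`GPRO_TYPE_2`
#'   mentions with validated offsets.
#' @export
gpro_predict <- function(model, corp, tagger = regex_tagger) {
  spba_ments <- if (model$use_spba) {
    spba_predict(model$spba, corp, model$ckb, tagger)
  } else NULL
  fc <- featurize_corpus(corp, spba_ments, model$use_spba, tagger)
  paths <- predict_crf(model$crf, fc$feats)
  out <- list()
  for (i in seq_along(paths)) {
    m <- fc$meta[[i]]
    dm <- decode_sobie(paths[[i]], m$tokens, doc_id = m$doc_id,
                       section = m$section, text = m$text)
    if (nrow(dm) > 0L) out[[length(out) + 1L]] <- dm
  }
  if (length(out) == 0L) return(mentions())
  res <- do.call(rbind, out)
  res <- res[order(res$doc_id, res$section, res$start), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("gpro_mentions", "data.frame")
  validate_mentions(res, corp)
  res
}
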