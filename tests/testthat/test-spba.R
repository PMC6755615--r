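# Pattern induction, approximate matching, match scoring and weight tuning.

spba_lexicon <- function() {
  data.frame(
    term = c("BanHI", "A", "transcripts", "transcription factor", "NF-kappaB",
             "human", "M-CSF", "promoter", "receptors", "A2A", "phosphatase",
             "genes", "nitric oxide", "synthase", "mRNA", "38-kD", "murine",
             "MAP", "kinase"),
    class = c("GeneSymbol", "Specifier", "RNAKeyword", "ProteinKeyword",
              "GeneSymbol", "Taxonomy", "GeneSymbol", "ProteinKeyword",
              "ProteinKeyword", "GeneSymbol", "Enzyme", "DNAKeyword",
              "Chemical", "Enzyme", "RNAKeyword", "Unit", "Taxonomy",
              "GeneSymbol", "Enzyme"),
    stringsAsFactors = FALSE)
}

test_that("pattern induction drops unlabeled words and keeps the best ratio", {
  ckb <- ckb_new(spba_lexicon())
  p <- generate_pattern(tokenize("BanHI A rightward transcripts"), ckb)
  expect_equal(p$concepts, c("GeneSymbol", "Specifier", "RNAKeyword"))
  expect_equal(p$labeled_ratio, 3 / 4)

  p2 <- generate_pattern(tokenize("transcription factor NF-kappaB"), ckb)
  expect_equal(p2$concepts, c("ProteinKeyword", "GeneSymbol"))
  expect_equal(p2$labeled_ratio, 1)

  expect_null(generate_pattern(tokenize("wholly unknown words"), ckb))
})

test_that("ratio ties resolve by class priority, confirmed by enumeration", {
  # "dux" is both GeneSymbol (Symbol group) and Chemical (Attribute group):
  # both labelings cover one of two words, so the ratios tie exactly
  lex <- data.frame(term = c("dux", "dux"),
                    class = c("Chemical", "GeneSymbol"), stringsAsFactors = FALSE)
  ckb <- ckb_new(lex, regexes = character(0))
  toks <- tokenize("dux filler")
  labelings <- spbacrf:::enumerate_labelings(ckb, toks)
  covered <- vapply(labelings, function(l) {
    if (nrow(l) == 0L) 0L else sum(l$token_end - l$token_start)
  }, 0L)
  best <- labelings[covered == max(covered)]
  expect_equal(length(best), 2L)              # the tie is real
  ratios <- vapply(best, function(l) sum(l$token_end - l$token_start) / 2, 0)
  expect_equal(ratios, rep(max(ratios), 2L))
  p <- generate_pattern(toks, ckb)
  expect_equal(p$concepts, "GeneSymbol")       # Symbol beats Attribute
  expect_equal(p$labeled_ratio, 0.5)
})

test_that("pattern sets deduplicate with counts in deterministic order", {
  ckb <- ckb_new(spba_lexicon())
  corp <- corpus("D1", abstract = "x")
  gold <- mentions(rep("D1", 3), "abstract", c(0L, 0L, 0L), c(1L, 1L, 1L),
                   c("human M-CSF promoter", "human M-CSF promoter",
                     "BanHI A transcripts"), "GENE")
  # offsets are irrelevant to induction; bypass validation intentionally
  ps <- generate_pattern_set(gold, ckb)
  expect_equal(length(ps), 2L)
  expect_equal(ps[[1]]$concepts, c("Taxonomy", "GeneSymbol", "ProteinKeyword"))
  expect_equal(ps[[1]]$count, 2L)
  expect_equal(ps[[2]]$count, 1L)

  expect_equal(generate_pattern_set(mentions(), ckb), list())
})

test_that("exact pattern matches anchor on labels with no edits", {
  ckb <- ckb_new(spba_lexicon())
  toks <- tokenize("the A2A receptors were blocked")
  labs <- label_sentence(ckb, toks)
  m <- match_pattern(list(concepts = c("GeneSymbol", "ProteinKeyword")),
                     labs, toks)
  expect_equal(length(m), 1L)
  expect_equal(m[[1]]$tok_start, 2L)
  expect_equal(m[[1]]$tok_end, 4L)
  expect_equal(unname(m[[1]]$features["n_matched"]), 2)
  expect_equal(unname(m[[1]]$features["n_inserted"]), 0)
  expect_equal(unname(m[[1]]$features["n_deleted"]), 0)
})

test_that("matching tolerates word insertions inside the span", {
  ckb <- ckb_new(spba_lexicon())
  toks <- tokenize("phosphatase 2A -sensitive genes")
  labs <- label_sentence(ckb, toks)
  m <- match_pattern(list(concepts = c("Enzyme", "Specifier", "DNAKeyword")),
                     labs, toks)
  expect_equal(length(m), 1L)
  expect_equal(sum(m[[1]]$alignment$op == "INSERT"), 1L)
  expect_equal(unname(m[[1]]$features["n_inserted"]), 1)
  expect_equal(m[[1]]$tok_start, 1L)
  expect_equal(m[[1]]$tok_end, 5L)
})

test_that("a pattern without an anchor in the sentence yields no match", {
  ckb <- ckb_new(spba_lexicon())
  toks <- tokenize("nothing relevant here")
  labs <- label_sentence(ckb, toks)
  expect_equal(match_pattern(list(concepts = "GeneSymbol"), labs, toks), list())
})

test_that("matching equals the brute-force alignment enumerator on random cases", {
  lex <- data.frame(
    term = c("ga", "gb", "pk", "tx", "ga gb"),
    class = c("GeneSymbol", "GeneSymbol", "ProteinKeyword", "Taxonomy",
              "GeneSymbol"),
    stringsAsFactors = FALSE)
  ckb <- ckb_new(lex, regexes = character(0))
  vocab <- c("ga", "gb", "pk", "tx", "uu", "vv")
  classes <- c("GeneSymbol", "ProteinKeyword", "Taxonomy")
  set.seed(23)
  for (rep in 1:60) {
    toks <- tokenize(paste(sample(vocab, sample(3:8, 1L), TRUE), collapse = " "),
                     tagger = identity_tagger)
    labs <- label_sentence(ckb, toks)
    concepts <- sample(classes, sample(1:4, 1L), TRUE)
    got <- match_pattern(list(concepts = concepts), labs, toks)
    want <- oracle_alignments(concepts, labs)
    got_spans <- sort(vapply(got, function(m) paste(m$tok_start, m$tok_end), ""))
    want_spans <- sort(unique(paste(want$tok_start, want$tok_end)))
    expect_equal(got_spans, want_spans,
                 info = paste(c(toks$surface, "|", concepts), collapse = " "))
    for (m in got) {
      cand <- want[want$tok_start == m$tok_start & want$tok_end == m$tok_end, ]
      expect_true(match_signature(m) %in% cand$match_sig)
    }
  }
})

test_that("match features are pure and carry context and morphology", {
  ckb <- ckb_new(spba_lexicon())
  toks <- tokenize("the A2A receptors were blocked")
  labs <- label_sentence(ckb, toks)
  m <- match_pattern(list(concepts = c("GeneSymbol", "ProteinKeyword")),
                     labs, toks)[[1]]
  f1 <- featurize_match(m, toks)
  f2 <- featurize_match(m, toks)
  expect_identical(f1, f2)
  expect_equal(unname(f1["wl=the"]), 1)
  expect_equal(unname(f1["wr=were"]), 1)
  expect_equal(unname(f1["m_has_digit"]), 1)   # "A2A"
  expect_equal(unname(f1["match=GeneSymbol"]), 1)
})

test_that("logistic scoring follows the closed form and is monotone", {
  expect_equal(score_match(c(x = 3), list(weights = c(x = 0), bias = 0)), 0.5)
  expect_equal(score_match(c(matched = 2),
                           list(weights = c(matched = 1), bias = -1)),
               plogis(1), tolerance = 1e-12)
  w <- list(weights = c(a = 0.7), bias = 0.1)
  s1 <- score_match(c(a = 1), w)
  s2 <- score_match(c(a = 2), w)
  expect_gt(s2, s1)
  # unknown feature names contribute zero weight
  expect_equal(score_match(c(a = 1, zz = 5), w), s1)
})

test_that("weight tuning reduces log loss and shrinks useless features", {
  logloss <- function(w, cand) {
    -mean(vapply(cand, function(cc) {
      p <- score_match(cc$features, w)
      if (isTRUE(cc$label)) log(p) else log(1 - p)
    }, 0))
  }
  set.seed(5)
  cand <- lapply(1:60, function(i) {
    lab <- i %% 2 == 0
    list(features = c(sig = as.numeric(lab) + rnorm(1, 0, 0.05),
                      junk = rnorm(1)), label = lab)
  })
  w <- tune_weights(cand, lambda = 1e-2)
  w0 <- list(weights = c(sig = 0, junk = 0), bias = 0)
  expect_lt(logloss(w, cand), logloss(w0, cand))

  # balanced labels, single useless feature: ridge pulls the weight to ~0,
  # matching a brute-force grid search over (weight, bias)
  cand2 <- lapply(1:200, function(i) {
    list(features = c(u = rnorm(1)), label = i %% 2 == 0)
  })
  w2 <- tune_weights(cand2, lambda = 1)
  grid <- expand.grid(b = seq(-1, 1, by = 0.01), b0 = seq(-1, 1, by = 0.01))
  pen_loss <- vapply(seq_len(nrow(grid)), function(g) {
    logloss(list(weights = c(u = grid$b[g]), bias = grid$b0[g]), cand2) +
      0.5 * 1 * grid$b[g]^2 / 1   # glmnet scales the penalty per observation
  }, 0)
  best <- grid[which.min(pen_loss), ]
  expect_equal(unname(w2$weights["u"]), best$b, tolerance = 0.05)
  expect_lt(abs(w2$weights["u"]), 0.1)

  expect_error(tune_weights(lapply(1:3, function(i) {
    list(features = c(a = 1), label = TRUE)
  })), "degenerate")
})

test_that("gene-mention prediction thresholds scores and resolves overlaps", {
  ckb <- ckb_new(spba_lexicon())
  txt <- "the A2A receptors were blocked"
  toks <- tokenize(txt)
  pats <- list(list(concepts = c("GeneSymbol", "ProteinKeyword")),
               list(concepts = "GeneSymbol"))
  # weights favoring two-concept matches
  w <- list(weights = c(n_matched = 2), bias = -2)
  got <- predict_gene_mentions(pats, w, toks, ckb = ckb, text = txt,
                               threshold = 0.5)
  expect_equal(nrow(got), 1L)
  expect_equal(got$text, "A2A receptors")
  expect_equal(got$etype, "GENE")
  expect_equal(substring(txt, got$start + 1L, got$end), got$text)

  # logistic scores are always < 1, so threshold 1 kills everything
  none <- predict_gene_mentions(pats, w, toks, ckb = ckb, text = txt,
                                threshold = 1)
  expect_equal(nrow(none), 0L)

  # two overlapping matches: only the higher-scoring survives
  got2 <- predict_gene_mentions(pats, w, toks, ckb = ckb, text = txt,
                                threshold = 0.2)
  expect_equal(nrow(got2), 1L)   # the single-concept match overlaps and loses
  expect_equal(got2$text, "A2A receptors")
})

test_that("weights serialize to JSON and back", {
  w <- list(weights = c(n_matched = 1.25, `wl=the` = -0.5), bias = 0.75)
  f <- withr::local_tempfile(fileext = ".json")
  write_weights(w, f)
  back <- read_weights(f)
  expect_equal(back$weights, w$weights)
  expect_equal(back$bias, w$bias)
})
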