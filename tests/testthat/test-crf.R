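# SOBIE encoding/decoding, feature extraction, CRF training and decoding.

test_that("SOBIE encoding follows the scheme definition", {
  txt <- "TNF binds its receptor complex"
  toks <- tokenize(txt, tagger = identity_tagger)
  m1 <- mentions("d", "abstract", 0L, 3L, "TNF", "GPRO_TYPE_1")
  expect_equal(encode_sobie(toks, m1),
               c("S-GPRO_TYPE_1", "O", "O", "O", "O"))
  m2 <- mentions("d", "abstract", 10L, 30L, "its receptor complex",
                 "GPRO_TYPE_2")
  expect_equal(encode_sobie(toks, m2),
               c("O", "O", "B-GPRO_TYPE_2", "I-GPRO_TYPE_2", "E-GPRO_TYPE_2"))

  both <- rbind(m1, m2)
  class(both) <- c("gpro_mentions", "data.frame")
  expect_equal(encode_sobie(toks, both),
               c("S-GPRO_TYPE_1", "O", "B-GPRO_TYPE_2", "I-GPRO_TYPE_2",
                 "E-GPRO_TYPE_2"))

  overlapping <- mentions(c("d", "d"), "abstract", c(0L, 0L), c(9L, 3L),
                          c("TNF binds", "TNF"), "GPRO_TYPE_1")
  expect_error(encode_sobie(toks, overlapping), "overlap")
})

test_that("encode/decode round-trips on random non-overlapping layouts", {
  set.seed(31)
  for (rep in 1:200) {
    lay <- random_layout(n_tokens = sample(4:14, 1L), n_ments = sample(0:3, 1L))
    labs <- encode_sobie(lay$tokens, lay$mentions)
    expect_true(all(labs %in% sobie_labels()))
    back <- decode_sobie(labs, lay$tokens, doc_id = "d1", text = lay$text)
    a <- lay$mentions[order(lay$mentions$start),
                      c("section", "start", "end", "text", "etype")]
    b <- back[order(back$start), c("section", "start", "end", "text", "etype")]
    rownames(a) <- rownames(b) <- NULL
    expect_equal(b, a)
  }
})

test_that("decoding repairs ill-formed label sequences", {
  toks <- tokenize("alpha beta gamma", tagger = identity_tagger)
  # leading I, then E: repaired as B..E, one two-token mention
  got <- decode_sobie(c("I-GPRO_TYPE_1", "E-GPRO_TYPE_1", "O"), toks,
                      text = "alpha beta gamma")
  expect_equal(nrow(got), 1L)
  expect_equal(got$text, "alpha beta")
  # unterminated B run closes at the last in-type token
  got2 <- decode_sobie(c("O", "B-GPRO_TYPE_2", "I-GPRO_TYPE_2"), toks,
                       text = "alpha beta gamma")
  expect_equal(got2$text, "beta gamma")
  expect_equal(got2$etype, "GPRO_TYPE_2")
  # type switch inside a run starts a new mention
  got3 <- decode_sobie(c("B-GPRO_TYPE_1", "I-GPRO_TYPE_2", "O"), toks,
                       text = "alpha beta gamma")
  expect_equal(got3$etype, c("GPRO_TYPE_1", "GPRO_TYPE_2"))
  expect_equal(decode_sobie(c("O", "O", "O"), toks, text = "alpha beta gamma"),
               mentions())
})

test_that("feature extraction normalizes digits and flags SPBA positions", {
  toks <- sub_tokenize_all(tokenize("IL-2 binds"))
  f <- extract_features(toks, spba_ments = NULL, use_spba = FALSE)
  expect_true("w0=il" %in% f[[1]])
  expect_true("w0=0" %in% f[[3]])       # the digit sub-token, normalized
  expect_true("o:has_digit" %in% f[[3]])
  expect_true("o:all_caps" %in% f[[1]])
  expect_true(any(grepl("^shape=", f[[1]])))

  # an SPBA mention covering the three "IL-2" sub-tokens: B, I, E positions
  sp <- mentions("d", "abstract", 0L, 4L, "IL-2", "GENE")
  f2 <- extract_features(toks, sp, use_spba = TRUE)
  expect_true("spba0=B" %in% f2[[1]])
  expect_true("spba0=I" %in% f2[[2]])
  expect_true("spba0=E" %in% f2[[3]])
  expect_true("spba0=O" %in% f2[[4]])

  # purity and schema stability: the SPBA group only adds spba features
  expect_identical(f2, extract_features(toks, sp, use_spba = TRUE))
  base <- lapply(f2, function(x) x[!grepl("^spba", x)])
  expect_identical(base, f)
})

test_that("word shape maps character classes", {
  expect_equal(spbacrf:::word_shape("p53"), "a00")
  expect_equal(spbacrf:::word_shape("VLA-4"), "AAA-0")
  expect_equal(spbacrf:::brief_shape("AAA-0"), "A-0")
})

make_tagged_corpus <- function(n_sent, seed) {
  # separable toy language: GENE<i> tokens are entities, everything else O
  set.seed(seed)
  fill <- c("binds", "with", "assay", "buffer", "under", "control", "then")
  sents <- list()
  for (i in seq_len(n_sent)) {
    words <- sample(fill, sample(4:7, 1L), TRUE)
    k <- sample(0:2, 1L)
    labp <- integer(0)
    if (k > 0) {
      at <- sort(sample(seq_along(words), k))
      for (j in rev(at)) {
        words <- append(words, sprintf("GENE%d", sample(1:20, 1L)), after = j)
      }
    }
    toks <- tokenize(paste(words, collapse = " "), tagger = identity_tagger)
    is_ent <- grepl("^GENE", toks$surface)
    lab <- ifelse(is_ent, "S-GPRO_TYPE_1", "O")
    sents[[i]] <- list(tokens = toks, labels = lab)
  }
  sents
}

test_that("the CRF learns a separable tagging task and decodes it", {
  sents <- make_tagged_corpus(120, seed = 7)
  feats <- lapply(sents, function(s) extract_features(s$tokens, use_spba = FALSE))
  labs <- lapply(sents, `[[`, "labels")
  tr <- 1:60; te <- 61:120
  model <- train_crf(feats[tr], labs[tr], l2 = 0.1, maxit = 100L)
  pred <- predict_crf(model, feats[te])
  correct <- sum(mapply(function(p, g) sum(p == g), pred, labs[te]))
  total <- sum(lengths(labs[te]))
  expect_gt(correct / total, 0.97)
  # entity recall specifically
  ent_hit <- sum(mapply(function(p, g) sum(p == g & g != "O"), pred, labs[te]))
  ent_tot <- sum(vapply(labs[te], function(g) sum(g != "O"), 0L))
  expect_gt(ent_hit / ent_tot, 0.9)
})

test_that("CRF training is deterministic and validates its contracts", {
  sents <- make_tagged_corpus(30, seed = 9)
  feats <- lapply(sents, function(s) extract_features(s$tokens, use_spba = FALSE))
  labs <- lapply(sents, `[[`, "labels")
  m1 <- train_crf(feats, labs, maxit = 40L)
  m2 <- train_crf(feats, labs, maxit = 40L)
  expect_identical(m1$par, m2$par)
  expect_identical(predict_crf(m1, feats), predict_crf(m2, feats))

  expect_error(train_crf(feats[1], list(labs[[1]][-1])), "labels")
  expect_error(train_crf(list(), list()), "at least one")
})

test_that("CRF gradient matches finite differences on a tiny problem", {
  sents <- make_tagged_corpus(3, seed = 3)
  feats <- lapply(sents, function(s) extract_features(s$tokens, use_spba = FALSE))
  labs <- lapply(sents, `[[`, "labels")
  dict <- sort(unique(unlist(feats)))
  xidx <- lapply(feats, function(sent) lapply(sent, function(f) match(f, dict)))
  ylab <- lapply(labs, function(l) match(l, sobie_labels()))
  L <- 9L; nfeat <- length(dict)
  npar <- nfeat * L + L * L + 2L * L
  set.seed(4)
  par <- rnorm(npar, sd = 0.1)
  res <- spbacrf:::.crf_negll_grad(par, xidx, ylab, nfeat, L, 0.5)
  for (k in sample(npar, 8L)) {
    eps <- 1e-6
    pp <- par; pp[k] <- pp[k] + eps
    pm <- par; pm[k] <- pm[k] - eps
    fd <- (spbacrf:::.crf_negll_grad(pp, xidx, ylab, nfeat, L, 0.5)$value -
             spbacrf:::.crf_negll_grad(pm, xidx, ylab, nfeat, L, 0.5)$value) /
      (2 * eps)
    expect_equal(res$grad[k], fd, tolerance = 1e-4)
  }
})
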