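# Deterministic synthetic fixtures: toy CKB lexicons, corpora with planted
# GPRO mentions, id/homolog tables and blacklists with the structure the
# recognizer assumes, so the whole pipeline trains and evaluates offline.
# Vocabulary is pronounceable nonsense plus the literal strings needed by
# the post-processing rule cases; no real gene names.

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

nonsense_words <- function(n, syllables = 2:3) {
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t",
            "v", "z", "st", "tr", "kl", "br")
  vow <- c("a", "e", "i", "o", "u", "or", "an", "el")
  out <- character(0)
  while (length(out) < n) {
    k <- if (length(syllables) == 1L) syllables else sample(syllables, 1L)
    w <- paste0(paste0(sample(cons, k, replace = TRUE),
                       sample(vow, k, replace = TRUE)), collapse = "")
    if (!w %in% out) out <- c(out, w)
  }
  out
}

# Gene symbols span the shape spectrum of real nomenclature: all-caps
# symbols, caps+digit, hyphen-digit forms, but also capitalized and plain
# lowercase word-like names whose shape is indistinguishable from ordinary
# vocabulary - so surface shape alone cannot identify them.
make_gene_symbols <- function(words) {
  n <- length(words)
  style <- sample(5L, n, replace = TRUE)
  sym <- character(n)
  for (i in seq_len(n)) {
    w <- words[i]
    sym[i] <- switch(style[i],
      toupper(substr(w, 1L, 4L)),
      paste0(toupper(substr(w, 1L, 4L)), sample(1:9, 1L)),
      paste0(toupper(substr(w, 1L, 2L)), "-", sample(1:9, 1L)),
      paste0(toupper(substr(w, 1L, 1L)), substr(w, 2L, nchar(w))),
      w)
  }
  keep <- !duplicated(sym)
  sym[keep]
}

#' Specification for a synthetic fixture set
#'
#' `seed` governs all randomness (same spec, byte-identical fixtures).
#' `type1_fraction` of the distinct planted mention surfaces receive exactly
#' one database id (gold `GPRO_TYPE_1`); the rest get zero or two ids.
#' `insertion_prob` plants an unlabeled word inside a mention (exercising
#' SPBA's insertion tolerance), `noise` controls distractor terms, and
#' `holdout_fraction` of gene symbols appear only in the second (test) half
#' of the corpus while still being present in the CKB lexicon - they are
#' dictionary-matchable but unseen at CRF training time.
#'
#' @param seed integer seed.
#' @param n_docs number of documents.
#' @param n_gene_symbols,n_taxonomy,n_filler vocabulary sizes.
#' @param templates list of concept-class sequences mentions instantiate.
#' @param type1_fraction fraction of mention surfaces with a unique id.
#' @param insertion_prob probability of an inserted word inside a mention.
#' @param noise distractor-term rate per sentence.
#' @param holdout_fraction fraction of gene symbols reserved for test docs.
#' @return A list of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 7L, n_docs = 200L, n_gene_symbols = 60L,
                         n_taxonomy = 8L, n_filler = 40L,
                         templates = list(
                           c("GeneSymbol"),
                           c("GeneSymbol", "ProteinKeyword"),
                           c("Taxonomy", "GeneSymbol", "ProteinKeyword"),
                           c("ProteinKeyword", "GeneSymbol")),
                         type1_fraction = 0.5, insertion_prob = 0.15,
                         noise = 0.1, holdout_fraction = 0.2) {
  if (n_docs < 2L) stop("invalid spec: need at least 2 documents")
  if (n_gene_symbols < 4L) stop("invalid spec: need at least 4 gene symbols")
  if (length(templates) == 0L) stop("invalid spec: need at least one mention template")
  if (type1_fraction < 0 || type1_fraction > 1) {
    stop("invalid spec: type1_fraction must be in [0,1]")
  }
  cls <- unique(unlist(templates))
  bad <- setdiff(cls, c("GeneSymbol", "ProteinKeyword", "Taxonomy"))
  if (length(bad) > 0L) {
    stop(sprintf("invalid spec: unsupported template class %s", bad[1L]))
  }
  structure(list(seed = as.integer(seed), n_docs = as.integer(n_docs),
                 n_gene_symbols = as.integer(n_gene_symbols),
                 n_taxonomy = as.integer(n_taxonomy),
                 n_filler = as.integer(n_filler), templates = templates,
                 type1_fraction = type1_fraction,
                 insertion_prob = insertion_prob, noise = noise,
                 holdout_fraction = holdout_fraction),
            class = "fixture_spec")
}

PROTEIN_KEYWORDS_FIX <- c("receptor", "factor", "kinase", "subunit")

#' Generate a complete synthetic fixture set
#'
#' Documents are patent-abstract-like: a one-sentence title and a short
#' abstract with planted mentions instantiating the template concept
#' sequences. The first half of the corpus is the conventional training
#' half; documents in the second half may use held-out gene symbols (see
#' [fixture_spec()]).
#'
#' @param spec a [fixture_spec()].
#' @return A list with `corpus`, `gold`, `lexicon` (term/class data frame),
#'   `ckb`, `id_df`, `homolog_df`, `id_tab` (an [id_table()]), `blacklist`,
#'   and the `spec`.
#' @export
generate_fixture <- function(spec = fixture_spec()) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, {
    pool <- nonsense_words(spec$n_gene_symbols + spec$n_taxonomy +
                             spec$n_filler + 6L + 10L, syllables = 2:3)
    gene_syms <- make_gene_symbols(pool[seq_len(spec$n_gene_symbols)])
    pool <- setdiff(pool[-seq_len(spec$n_gene_symbols)], gene_syms)
    n_hold <- max(1L, round(spec$holdout_fraction * length(gene_syms)))
    holdout <- gene_syms[seq_len(n_hold)]
    trainsyms <- setdiff(gene_syms, holdout)
    taxonomy <- pool[seq_len(spec$n_taxonomy)]
    pool <- pool[-seq_len(spec$n_taxonomy)]
    filler <- head(pool, spec$n_filler)
    chemicals <- utils::tail(pool, 6L)   # distractors, also the blacklist

    lexicon <- rbind(
      data.frame(term = gene_syms, class = "GeneSymbol", stringsAsFactors = FALSE),
      data.frame(term = taxonomy, class = "Taxonomy", stringsAsFactors = FALSE),
      data.frame(term = PROTEIN_KEYWORDS_FIX, class = "ProteinKeyword",
                 stringsAsFactors = FALSE),
      data.frame(term = chemicals, class = "Chemical", stringsAsFactors = FALSE))
    ckb <- ckb_new(lexicon)

    vocab_for <- function(cls, test_half) {
      switch(cls,
             GeneSymbol = if (test_half && runif(1) < 0.4) sample(holdout, 1L)
                          else sample(trainsyms, 1L),
             ProteinKeyword = sample(PROTEIN_KEYWORDS_FIX, 1L),
             Taxonomy = sample(taxonomy, 1L))
    }

    make_mention_words <- function(test_half) {
      tmpl <- spec$templates[[sample(length(spec$templates), 1L)]]
      words <- vapply(tmpl, vocab_for, "", test_half = test_half)
      if (length(words) > 1L && runif(1) < spec$insertion_prob) {
        at <- sample(length(words) - 1L, 1L)
        words <- append(words, sample(filler, 1L), after = at)
      }
      words
    }

    doc_rows <- vector("list", spec$n_docs)
    gold_rows <- list()
    surface_set <- character(0)

    build_sentence <- function(n_ment, test_half, doc_id, section, offset0) {
      words <- sample(filler, sample(4:7, 1L), replace = TRUE)
      if (runif(1) < spec$noise) {
        words <- append(words, sample(chemicals, 1L),
                        after = sample(length(words), 1L))
      }
      ment_words <- replicate(n_ment, make_mention_words(test_half),
                              simplify = FALSE)
      # place mentions at distinct word gaps, at least one word apart
      slots <- sort(sample(seq_len(length(words) - 1L), n_ment))
      pieces <- character(0)
      ments_local <- list()
      pos <- 0L
      cursor <- offset0
      append_piece <- function(txt) {
        pre <- if (length(pieces) > 0L) " " else ""
        pieces <<- c(pieces, paste0(pre, txt))
        start <- cursor + if (length(pieces) > 1L) 1L else 0L
        cursor <<- start + nchar(txt)
        c(start, cursor)
      }
      mi <- 1L
      for (w in seq_along(words)) {
        wtxt <- words[w]
        if (w == 1L) wtxt <- paste0(toupper(substr(wtxt, 1, 1)), substr(wtxt, 2, nchar(wtxt)))
        append_piece(wtxt)
        if (mi <= n_ment && w == slots[mi]) {
          mtxt <- paste(ment_words[[mi]], collapse = " ")
          sp <- append_piece(mtxt)
          ments_local[[mi]] <- data.frame(doc_id = doc_id, section = section,
                                          start = sp[1L], end = sp[2L],
                                          text = mtxt, stringsAsFactors = FALSE)
          mi <- mi + 1L
        }
      }
      pieces <- c(pieces, ".")
      cursor <- cursor + 1L
      list(text = paste(pieces, collapse = ""), ments = ments_local,
           end = cursor)
    }

    for (d in seq_len(spec$n_docs)) {
      doc_id <- sprintf("D%04d", d)
      test_half <- d > spec$n_docs %/% 2L
      ti <- build_sentence(sample(0:1, 1L, prob = c(0.6, 0.4)), test_half,
                           doc_id, "title", 0L)
      nsent <- sample(2:3, 1L)
      abs_parts <- character(0)
      abs_ments <- list()
      cur <- 0L
      for (s in seq_len(nsent)) {
        sn <- build_sentence(sample(0:2, 1L, prob = c(0.2, 0.5, 0.3)),
                             test_half, doc_id, "abstract", cur)
        abs_parts <- c(abs_parts, sn$text)
        abs_ments <- c(abs_ments, sn$ments)
        cur <- sn$end + 1L   # single joining space
      }
      abstract <- paste(abs_parts, collapse = " ")
      doc_rows[[d]] <- data.frame(doc_id = doc_id, title = ti$text,
                                  abstract = abstract, stringsAsFactors = FALSE)
      gold_rows <- c(gold_rows, ti$ments, abs_ments)
    }

    corp <- do.call(rbind, doc_rows)
    corp <- corpus(corp$doc_id, corp$title, corp$abstract)
    gr <- do.call(rbind, gold_rows)

    # type assignment per distinct surface; exactly the type1 fraction of
    # surfaces get one id
    surfaces <- sort(unique(gr$text))
    n1 <- round(spec$type1_fraction * length(surfaces))
    type1_surf <- sample(surfaces, n1)
    etype <- ifelse(gr$text %in% type1_surf, "GPRO_TYPE_1", "GPRO_TYPE_2")
    gold <- mentions(gr$doc_id, gr$section, gr$start, gr$end, gr$text, etype)
    validate_mentions(gold, corp)

    # id and homolog tables consistent with the gold types
    id_rows <- list()
    hom_rows <- list()
    idc <- 0L
    next_id <- function() { idc <<- idc + 1L; sprintf("ID%05d", idc) }
    for (s in surfaces) {
      if (s %in% type1_surf) {
        if (runif(1) < 0.25) {
          # two homolog ids collapsing to one human id: still Type 1
          hid <- next_id(); mid <- next_id()
          id_rows[[length(id_rows) + 1L]] <- data.frame(term = s, class = hid)
          id_rows[[length(id_rows) + 1L]] <- data.frame(term = s, class = mid)
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(term = mid, class = hid)
          hom_rows[[length(hom_rows) + 1L]] <- data.frame(term = hid, class = hid)
        } else {
          id_rows[[length(id_rows) + 1L]] <- data.frame(term = s, class = next_id())
        }
      } else if (runif(1) < 0.5) {
        id_rows[[length(id_rows) + 1L]] <- data.frame(term = s, class = next_id())
        id_rows[[length(id_rows) + 1L]] <- data.frame(term = s, class = next_id())
      }   # else: no ids at all
    }
    id_df <- if (length(id_rows) > 0L) do.call(rbind, id_rows) else
      data.frame(term = character(0), class = character(0))
    homolog_df <- if (length(hom_rows) > 0L) do.call(rbind, hom_rows) else
      data.frame(term = character(0), class = character(0))
    nm <- unique(id_df$term)
    id_tab <- id_table(nm, lapply(nm, function(x) id_df$class[id_df$term == x]),
                       setNames(homolog_df$class, homolog_df$term))

    list(corpus = corp, gold = gold, lexicon = lexicon, ckb = ckb,
         id_df = id_df, homolog_df = homolog_df, id_tab = id_tab,
         blacklist = chemicals, holdout_symbols = holdout, spec = spec)
  })
}

#' Documents exercising each post-processing rule
#'
#' One document per annotation-standard rule, each containing the canonical
#' construction with its pre-rule annotation and the expected post-rule
#' annotation: the full-name/abbreviation "receptor" merge, the two-token
#' "... protein" trim, the short-name "protein" absorption, and a tag
#' consistency case.
#'
#' @return A list with `corpus`, `pre` (annotations before post-processing)
#'   and `expected` (annotations afterwards).
#' @export
plant_rule_cases <- function() {
  corp <- corpus(
    c("R1", "R2", "R3", "R4"),
    title = c("Receptor merge case", "Two token trim case",
              "Short name expansion case", "Tag consistency case"),
    abstract = c(
      "The epidermal growth factor (EGF) receptor pathway is active.",
      "The p53 protein level was measured.",
      "The AR protein level was measured.",
      "ZORB binds the promoter. Binding of ZORB was reduced."))
  span <- function(doc, s) {
    txt <- section_text(corp, doc, "abstract")
    st <- regexpr(s, txt, fixed = TRUE)[[1L]] - 1L
    c(st, st + nchar(s))
  }
  pre <- rbind(
    {sp <- span("R1", "epidermal growth factor")
     mentions("R1", "abstract", sp[1], sp[2], "epidermal growth factor", "GPRO_TYPE_1")},
    {sp <- span("R1", "EGF")
     mentions("R1", "abstract", sp[1], sp[2], "EGF", "GPRO_TYPE_1")},
    {sp <- span("R2", "p53 protein")
     mentions("R2", "abstract", sp[1], sp[2], "p53 protein", "GPRO_TYPE_1")},
    {sp <- span("R3", "AR")
     mentions("R3", "abstract", sp[1], sp[2], "AR", "GPRO_TYPE_1")},
    {sp <- span("R4", "ZORB")
     mentions("R4", "abstract", sp[1], sp[2], "ZORB", "GPRO_TYPE_1")})
  class(pre) <- c("gpro_mentions", "data.frame")
  expected <- rbind(
    {sp <- span("R1", "epidermal growth factor (EGF) receptor")
     mentions("R1", "abstract", sp[1], sp[2],
              "epidermal growth factor (EGF) receptor", "GPRO_TYPE_1")},
    {sp <- span("R2", "p53")
     mentions("R2", "abstract", sp[1], sp[2], "p53", "GPRO_TYPE_1")},
    {sp <- span("R3", "AR protein")
     mentions("R3", "abstract", sp[1], sp[2], "AR protein", "GPRO_TYPE_1")},
    {sp <- span("R4", "ZORB")
     mentions("R4", "abstract", sp[1], sp[2], "ZORB", "GPRO_TYPE_1")},
    {txt <- section_text(corp, "R4", "abstract")
     st <- regexpr("ZORB was", txt, fixed = TRUE)[[1L]] - 1L
     mentions("R4", "abstract", st, st + 4L, "ZORB", "GPRO_TYPE_1")})
  class(expected) <- c("gpro_mentions", "data.frame")
  validate_mentions(pre, corp)
  validate_mentions(expected, corp)
  list(corpus = corp, pre = pre, expected = expected)
}

#' Write a fixture set to a directory in the package's file formats
#'
#' @param fx a fixture list from [generate_fixture()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(fx, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_corpus(fx$corpus, file.path(dir, "corpus.tsv"))
  write_annotations(fx$gold, file.path(dir, "gold.tsv"))
  write_lexicon(fx$lexicon, file.path(dir, "lexicon.tsv"))
  write_lexicon(fx$id_df, file.path(dir, "id_table.tsv"))
  write_lexicon(fx$homolog_df, file.path(dir, "homolog.tsv"))
  writeLines(fx$blacklist, file.path(dir, "blacklist.txt"))
  invisible(dir)
}
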