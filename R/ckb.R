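# Concept Knowledge Base: term lexicons organized for leftmost-longest
# prefix matching, plus regular-expression concept classes applied to
# single tokens the lexicon pass leaves unlabeled.

CKB_GROUPS <- list(
  Symbol    = c("CellLineSymbol", "CellTypeSymbol", "ChromosomeSymbol",
                "GeneSymbol"),
  NEKeyword = c("CellKeyword", "CellLineKeyword", "DNAKeyword",
                "ProteinKeyword", "RNAKeyword", "Enzyme"),
  Attribute = c("BiologicalProcess", "Chemical", "Disease", "Morphology",
                "OrganTissue", "Taxonomy", "Structure", "Unit"),
  Others    = c("Conjunction", "Preposition", "Specifier")
)

CKB_CLASSES <- unlist(CKB_GROUPS, use.names = FALSE)

# lower rank = higher priority when one term carries several classes
class_priority <- function(cls) {
  grp <- rep(5L, length(cls))
  for (g in seq_along(CKB_GROUPS)) grp[cls %in% CKB_GROUPS[[g]]] <- g
  grp
}

#' Default regular-expression concept classes
#'
#' Concept classes whose membership is a pattern rather than a term list:
#' chromosome locus symbols like `"11p15"`/`"14q32.1"` and specifiers such
#' as Greek letters, Roman numerals and short alphanumeric qualifiers like
#' `"2A"`. Users may override or extend these when building a CKB.
#'
#' @return Named character vector, class name to regex.
#' @export
default_ckb_regexes <- function() {
  c(ChromosomeSymbol = "^[0-9]{1,2}[pq][0-9]+(\\.[0-9]+)?$",
    Specifier = "^(alpha|beta|gamma|delta|epsilon|kappa|I{1,3}|IV|V|VI{0,3}|[A-Z]|[0-9]{1,2}[A-Z]?)$")
}

# matching normalization: terms of >= 4 characters match case-insensitively,
# shorter terms (symbols like "AR") match case-sensitively
CKB_CASE_MIN <- 4L

term_tokens <- function(term) {
  tokenize(term, tagger = identity_tagger)$surface
}

#' Build a Concept Knowledge Base
#'
#' @param lexicon data frame with columns `term` and `class`; multi-word
#'   terms are tokenized with the package tokenizer. Duplicate
#'   (term, class) rows collapse to one entry.
#' @param regexes named character vector mapping class names to regexes
#'   applied to single unlabeled tokens; defaults to
#'   [default_ckb_regexes()]. Use `character(0)` for none.
#' @return An object of class `ckb`.
#' @export
ckb_new <- function(lexicon = data.frame(term = character(0), class = character(0)),
                    regexes = default_ckb_regexes()) {
  if (nrow(lexicon) > 0L) {
    bad <- setdiff(unique(lexicon$class), CKB_CLASSES)
    if (length(bad) > 0L) {
      stop(sprintf("unknown concept class in lexicon: %s",
                   paste(bad, collapse = ", ")))
    }
  }
  if (length(regexes) > 0L) {
    bad <- setdiff(names(regexes), CKB_CLASSES)
    if (length(bad) > 0L) {
      stop(sprintf("unknown concept class in regex specs: %s",
                   paste(bad, collapse = ", ")))
    }
  }
  lexicon <- unique(lexicon[, c("term", "class")])
  toks <- lapply(lexicon$term, term_tokens)
  key <- vapply(toks, paste, "", collapse = " ")
  ntok <- lengths(toks)
  keep <- ntok > 0L
  lexicon <- lexicon[keep, , drop = FALSE]
  key <- key[keep]; ntok <- ntok[keep]
  ci <- nchar(key) >= CKB_CASE_MIN
  exact <- new.env(parent = emptyenv())
  lower <- new.env(parent = emptyenv())
  add <- function(env, k, cls) assign(k, unique(c(env[[k]], cls)), envir = env)
  for (i in seq_along(key)) {
    if (ci[i]) add(lower, tolower(key[i]), lexicon$class[i])
    else add(exact, key[i], lexicon$class[i])
  }
  structure(list(
    lexicon = lexicon,
    exact = exact, lower = lower,
    max_ntok = if (length(ntok) > 0L) max(ntok) else 0L,
    regexes = regexes,
    n_entries = nrow(lexicon)
  ), class = "ckb")
}

#' @export
print.ckb <- function(x, ...) {
  cat(sprintf("<ckb> %d lexicon entries (%d classes), %d regex classes\n",
              x$n_entries, length(unique(x$lexicon$class)), length(x$regexes)))
  invisible(x)
}

#' Load a CKB from lexicon files
#'
#' @param lexicon_paths character vector of 2-column TSV lexicon files
#'   (term, concept class).
#' @param regexes regex class specs as in [ckb_new()].
#' @return A `ckb` object.
#' @export
load_ckb <- function(lexicon_paths, regexes = default_ckb_regexes()) {
  lex <- do.call(rbind, lapply(lexicon_paths, read_lexicon))
  if (is.null(lex)) lex <- data.frame(term = character(0), class = character(0))
  ckb_new(lex, regexes)
}

# classes for the phrase spanning token surfaces, NULL when absent
ckb_lookup <- function(ckb, phrase) {
  cls <- ckb$exact[[phrase]]
  if (nchar(phrase) >= CKB_CASE_MIN) {
    cls <- c(cls, ckb$lower[[tolower(phrase)]])
  }
  if (length(cls) == 0L) NULL else unique(cls)
}

ckb_regex_class <- function(ckb, surface) {
  for (i in seq_along(ckb$regexes)) {
    if (grepl(ckb$regexes[[i]], surface)) return(names(ckb$regexes)[i])
  }
  NULL
}

best_class <- function(classes) {
  classes[order(class_priority(classes), classes)][1L]
}

empty_labels <- function() {
  data.frame(concept = character(0), token_start = integer(0),
             token_end = integer(0), matched_term = character(0),
             stringsAsFactors = FALSE)
}

# all (length, class) lexicon/regex matches starting at token i
matches_at <- function(ckb, surfaces, i) {
  n <- length(surfaces)
  out <- list()
  maxlen <- min(ckb$max_ntok, n - i + 1L)
  for (len in seq_len(max(maxlen, 0L))) {
    phrase <- paste(surfaces[i:(i + len - 1L)], collapse = " ")
    cls <- ckb_lookup(ckb, phrase)
    if (!is.null(cls)) {
      for (cl in cls) out[[length(out) + 1L]] <- list(len = len, class = cl)
    }
  }
  if (length(out) == 0L) {
    rc <- ckb_regex_class(ckb, surfaces[i])
    if (!is.null(rc)) out[[1L]] <- list(len = 1L, class = rc)
  }
  out
}

#' Label a token sequence with CKB concept classes
#'
#' Greedy leftmost-longest labeling: at each position the longest lexicon
#' phrase wins (class ties broken by the fixed priority Symbol > NEKeyword >
#' Attribute > Others, then alphabetically); tokens the lexicon leaves
#' unlabeled are tried against the regex classes one token at a time.
#' Returned labels never overlap.
#'
#' @param ckb a `ckb` object.
#' @param tokens a `gpro_tokens` data frame (ordered, non-overlapping).
#' @return A data frame with columns `concept`, `token_start`, `token_end`
#'   (1-based, half-open token indices) and `matched_term`.
#' @export
label_sentence <- function(ckb, tokens) {
  n <- nrow(tokens)
  if (n == 0L) return(empty_labels())
  surfaces <- tokens$surface
  rows <- list()
  i <- 1L
  while (i <= n) {
    m <- matches_at(ckb, surfaces, i)
    if (length(m) == 0L) { i <- i + 1L; next }
    lens <- vapply(m, `[[`, 0L, "len")
    best_len <- max(lens)
    cls <- vapply(m[lens == best_len], `[[`, "", "class")
    rows[[length(rows) + 1L]] <- data.frame(
      concept = best_class(cls), token_start = i, token_end = i + best_len,
      matched_term = paste(surfaces[i:(i + best_len - 1L)], collapse = " "),
      stringsAsFactors = FALSE)
    i <- i + best_len
  }
  if (length(rows) == 0L) return(empty_labels())
  do.call(rbind, rows)
}

#' Project concept labels to their class-name sequence
#'
#' @param labels a label data frame as returned by [label_sentence()],
#'   sorted by `token_start`.
#' @return Character vector of concept class names, one per label.
#' @export
concept_sequence <- function(labels) {
  if (nrow(labels) == 0L) return(character(0))
  if (is.unsorted(labels$token_start, strictly = TRUE)) {
    stop("labels must be sorted by token_start")
  }
  labels$concept
}

# Enumerate every non-overlapping labeling of a short token sequence.
# Each labeling is a label data frame; used by pattern generation to pick
# the labeling with the most labeled words.
enumerate_labelings <- function(ckb, tokens) {
  n <- nrow(tokens)
  surfaces <- tokens$surface
  recurse <- function(i) {
    if (i > n) return(list(empty_labels()))
    out <- list()
    for (rest in recurse(i + 1L)) out[[length(out) + 1L]] <- rest  # token i unlabeled
    for (m in matches_at_all(ckb, surfaces, i)) {
      row <- data.frame(concept = m$class, token_start = i,
                        token_end = i + m$len,
                        matched_term = paste(surfaces[i:(i + m$len - 1L)], collapse = " "),
                        stringsAsFactors = FALSE)
      for (rest in recurse(i + m$len)) {
        out[[length(out) + 1L]] <- rbind(row, rest)
      }
    }
    out
  }
  recurse(1L)
}

# like matches_at but regex classes always compete (pattern generation must
# see every labeling option, not only lexicon-first)
matches_at_all <- function(ckb, surfaces, i) {
  n <- length(surfaces)
  out <- list()
  maxlen <- min(ckb$max_ntok, n - i + 1L)
  for (len in seq_len(max(maxlen, 0L))) {
    phrase <- paste(surfaces[i:(i + len - 1L)], collapse = " ")
    for (cl in ckb_lookup(ckb, phrase)) {
      out[[length(out) + 1L]] <- list(len = len, class = cl)
    }
  }
  rc <- ckb_regex_class(ckb, surfaces[i])
  if (!is.null(rc)) out[[length(out) + 1L]] <- list(len = 1L, class = rc)
  out
}
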