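#' @useDynLib spbacrf, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optim plogis setNames runif
#' @importFrom utils head tail
NULL

# All character offsets in this package are 0-based, half-open, and relative
# to the section (title or abstract) they index into. substr() is 1-based, so
# slicing always goes through slice_text().

slice_text <- function(text, start, end) {
  substring(text, start + 1L, end)
}

#' Create a corpus data frame
#'
#' A corpus is a data frame with one row per document and columns `doc_id`,
#' `title`, `abstract`. Document ids must be unique and non-empty; titles and
#' abstracts may be empty strings but not `NA`.
#'
#' @param doc_id character vector of unique document ids.
#' @param title,abstract character vectors, recycled to `length(doc_id)`.
#' @return A `data.frame` of class `gpro_corpus`.
#' @export
corpus <- function(doc_id, title = "", abstract = "") {
  doc_id <- as.character(doc_id)
  if (any(!nzchar(doc_id)) || anyNA(doc_id)) {
    stop("doc_id must be non-empty")
  }
  if (anyDuplicated(doc_id)) {
    stop("doc_id values must be unique within a corpus")
  }
  title <- rep_len(as.character(title), length(doc_id))
  abstract <- rep_len(as.character(abstract), length(doc_id))
  if (anyNA(title) || anyNA(abstract)) stop("title/abstract may not be NA")
  out <- data.frame(doc_id = doc_id, title = title, abstract = abstract,
                    stringsAsFactors = FALSE)
  class(out) <- c("gpro_corpus", "data.frame")
  out
}

#' Read a corpus from a 3-column TSV file
#'
#' The file format is tab-separated with no header: `doc_id`, `title`,
#' `abstract`, one document per line, UTF-8.
#'
#' @param path path to the corpus file.
#' @return A `gpro_corpus` data frame, file order preserved.
#' @export
read_corpus <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines) | seq_along(lines) < length(lines)]
  if (length(lines) == 0L) {
    return(corpus(character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nfld <- lengths(parts)
  # a trailing empty abstract drops the final field in strsplit
  parts[nfld == 2L] <- lapply(parts[nfld == 2L], function(p) c(p, ""))
  nfld <- lengths(parts)
  bad <- which(nfld != 3L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed corpus line %d: expected 3 tab-separated fields, got %d",
                 bad[1L], nfld[bad[1L]]))
  }
  m <- do.call(rbind, parts)
  corpus(m[, 1L], m[, 2L], m[, 3L])
}

#' Write a corpus to a 3-column TSV file
#'
#' @param x a `gpro_corpus` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(x, path) {
  check_no_tabs(c(x$doc_id, x$title, x$abstract))
  writeLines(paste(x$doc_id, x$title, x$abstract, sep = "\t"), path,
             useBytes = TRUE)
  invisible(path)
}

check_no_tabs <- function(x) {
  if (any(grepl("[\t\n\r]", x))) {
    stop("fields may not contain tab or newline characters")
  }
  invisible(TRUE)
}

ETYPES <- c("GPRO_TYPE_1", "GPRO_TYPE_2", "GENE")
SECTIONS <- c("title", "abstract")

#' Create a mention data frame
#'
#' A mention set is a data frame with columns `doc_id`, `section` (`"title"`
#' or `"abstract"`), `start`, `end` (0-based half-open character offsets into
#' the section text), `text`, and `etype` (`GPRO_TYPE_1`, `GPRO_TYPE_2`, or
#' the SPBA-internal `GENE`).
#'
#' @param doc_id,section,start,end,text,etype column vectors (recycled).
#' @return A `data.frame` of class `gpro_mentions`.
#' @export
mentions <- function(doc_id = character(0), section = character(0),
                     start = integer(0), end = integer(0),
                     text = character(0), etype = character(0)) {
  n <- max(length(doc_id), length(section), length(start), length(end),
           length(text), length(etype))
  if (length(doc_id) == 0L) n <- 0L
  out <- data.frame(
    doc_id = rep_len(as.character(doc_id), n),
    section = rep_len(as.character(section), n),
    start = rep_len(as.integer(start), n),
    end = rep_len(as.integer(end), n),
    text = rep_len(as.character(text), n),
    etype = rep_len(as.character(etype), n),
    stringsAsFactors = FALSE
  )
  if (n > 0L) {
    if (!all(out$section %in% SECTIONS)) stop("section must be 'title' or 'abstract'")
    if (!all(out$etype %in% ETYPES)) stop(paste("etype must be one of:", paste(ETYPES, collapse = ", ")))
    if (any(out$start >= out$end)) stop("mention spans must satisfy start < end")
  }
  class(out) <- c("gpro_mentions", "data.frame")
  out
}

#' Validate mention offsets against a corpus
#'
#' Asserts offset integrity: for every mention, the stored text must equal
#' the slice of its document section. Used as a global validator after every
#' pipeline stage.
#'
#' @param ments a `gpro_mentions` data frame.
#' @param corp a `gpro_corpus` data frame.
#' @return `ments`, invisibly, if valid; otherwise an error.
#' @export
validate_mentions <- function(ments, corp) {
  if (nrow(ments) == 0L) return(invisible(ments))
  idx <- match(ments$doc_id, corp$doc_id)
  if (anyNA(idx)) {
    stop(sprintf("mention references unknown doc_id '%s'",
                 ments$doc_id[which(is.na(idx))[1L]]))
  }
  sect_text <- ifelse(ments$section == "title", corp$title[idx], corp$abstract[idx])
  ok <- ments$end <= nchar(sect_text) &
    slice_text(sect_text, ments$start, ments$end) == ments$text
  if (!all(ok)) {
    b <- which(!ok)[1L]
    stop(sprintf(
      "offset mismatch in doc '%s' %s [%d,%d): stored text %s does not equal the document slice",
      ments$doc_id[b], ments$section[b], ments$start[b], ments$end[b],
      deparse(ments$text[b])))
  }
  invisible(ments)
}

#' Read standoff annotations from a 6-column TSV file
#'
#' Format: `doc_id`, `section`, `start`, `end`, `text`, `etype`, tab
#' separated, no header. Every mention is validated against its document
#' text (see [validate_mentions()]).
#'
#' @param path annotation file path.
#' @param corp the corpus the annotations refer to.
#' @return A `gpro_mentions` data frame.
#' @export
read_annotations <- function(path, corp) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(mentions())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 6L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed annotation line %d: expected 6 tab-separated fields, got %d",
                 bad[1L], lengths(parts)[bad[1L]]))
  }
  m <- do.call(rbind, parts)
  out <- mentions(m[, 1L], m[, 2L], as.integer(m[, 3L]), as.integer(m[, 4L]),
                  m[, 5L], m[, 6L])
  validate_mentions(out, corp)
  out
}

#' Write standoff annotations to TSV
#'
#' @param ments a `gpro_mentions` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ments, path) {
  check_no_tabs(ments$text)
  writeLines(paste(ments$doc_id, ments$section, ments$start, ments$end,
                   ments$text, ments$etype, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

#' Read a 2-column lexicon TSV (term, concept class)
#'
#' @param path lexicon file path.
#' @return A data frame with columns `term` and `class`.
#' @export
read_lexicon <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(term = character(0), class = character(0),
                      stringsAsFactors = FALSE))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) != 2L)
  if (length(bad) > 0L) {
    stop(sprintf("malformed lexicon line %d: expected 2 fields", bad[1L]))
  }
  m <- do.call(rbind, parts)
  data.frame(term = m[, 1L], class = m[, 2L], stringsAsFactors = FALSE)
}

#' Write a lexicon TSV
#' @param lex data frame with `term`, `class` columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_lexicon <- function(lex, path) {
  check_no_tabs(c(lex$term, lex$class))
  writeLines(paste(lex$term, lex$class, sep = "\t"), path, useBytes = TRUE)
  invisible(path)
}

# Token regex: a word may start with a hyphen glued to it ("-sensitive"),
# and may contain internal connector characters between alphanumerics
# ("VLA-4", "3.4.14.5", "NF-kappaB"); anything else is a single-character
# token (parentheses, commas, stray punctuation).
TOKEN_REGEX <- "-?[A-Za-z0-9]+(?:[-'/._][A-Za-z0-9]+)*|\\S"

#' Tokenize text with character offsets
#'
#' Splits text into tokens (words keep internal hyphens/periods between
#' alphanumerics; other punctuation becomes single-character tokens) and
#' records 0-based half-open character offsets. POS and chunk tags come from
#' a pluggable tagger function.
#'
#' @param text a single string.
#' @param tagger a function `(data.frame of tokens) -> list(pos=, chunk=)`;
#'   defaults to [regex_tagger()]. Use [identity_tagger()] for a no-op.
#' @return A data frame of class `gpro_tokens` with columns `surface`,
#'   `start`, `end`, `pos`, `chunk`.
#' @export
tokenize <- function(text, tagger = regex_tagger) {
  stopifnot(length(text) == 1L)
  if (is.na(text) || !nzchar(text)) return(empty_tokens())
  m <- gregexpr(TOKEN_REGEX, text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(empty_tokens())
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  end <- start + len
  surface <- substring(text, start + 1L, end)
  out <- data.frame(surface = surface, start = start, end = end,
                    pos = "", chunk = "", stringsAsFactors = FALSE)
  tags <- tagger(out)
  out$pos <- tags$pos
  out$chunk <- tags$chunk
  class(out) <- c("gpro_tokens", "data.frame")
  out
}

empty_tokens <- function() {
  out <- data.frame(surface = character(0), start = integer(0),
                    end = integer(0), pos = character(0),
                    chunk = character(0), stringsAsFactors = FALSE)
  class(out) <- c("gpro_tokens", "data.frame")
  out
}

#' Split text into sentences
#'
#' Rule-based: a sentence boundary is a run of `.`, `!` or `?` followed by
#' whitespace and an uppercase letter. Returns 0-based half-open character
#' spans covering the trimmed sentences.
#'
#' @param text a single string.
#' @return A data frame with columns `start`, `end`.
#' @export
split_sentences <- function(text) {
  if (is.na(text) || !nzchar(trimws(text))) {
    return(data.frame(start = integer(0), end = integer(0)))
  }
  m <- gregexpr("[.!?]+[ \t]+(?=[A-Z])", text, perl = TRUE)[[1L]]
  cut_after <- integer(0)
  if (m[1L] != -1L) {
    # boundary sits after the punctuation run, before the whitespace
    punct_len <- attr(m, "match.length") -
      nchar(sub("^[.!?]+", "", regmatches(text, list(m))[[1L]]))
    cut_after <- as.integer(m) - 1L + punct_len
  }
  starts <- c(0L, cut_after)
  ends <- c(cut_after, nchar(text))
  spans <- data.frame(start = starts, end = ends)
  # trim whitespace at span edges
  for (i in seq_len(nrow(spans))) {
    s <- slice_text(text, spans$start[i], spans$end[i])
    lead <- nchar(s) - nchar(sub("^\\s+", "", s))
    trail <- nchar(s) - nchar(sub("\\s+$", "", s))
    spans$start[i] <- spans$start[i] + lead
    spans$end[i] <- spans$end[i] - trail
  }
  spans[spans$start < spans$end, , drop = FALSE]
}

char_class <- function(ch) {
  ifelse(grepl("[A-Za-z]", ch), "L", ifelse(grepl("[0-9]", ch), "D", "O"))
}

#' Split a token into sub-tokens at character-class boundaries
#'
#' Sub-tokens partition the token's span at transitions between letters,
#' digits and other characters; every non-alphanumeric character becomes its
#' own sub-token. Offsets remain valid against the original text.
#'
#' @param token a one-row `gpro_tokens` data frame (or a row slice).
#' @return A `gpro_tokens` data frame whose concatenated surfaces reproduce
#'   the parent token surface.
#' @export
sub_tokenize <- function(token) {
  surface <- token$surface
  chars <- strsplit(surface, "")[[1L]]
  cls <- char_class(chars)
  n <- length(chars)
  if (n == 0L) return(empty_tokens())
  new_piece <- c(TRUE, cls[-1L] != cls[-n] | cls[-1L] == "O" | cls[-n] == "O")
  piece <- cumsum(new_piece)
  starts <- token$start + which(new_piece) - 1L
  ends <- c(starts[-1L], token$start + n)
  out <- data.frame(
    surface = vapply(split(chars, piece), paste, "", collapse = ""),
    start = starts, end = ends,
    pos = token$pos, chunk = token$chunk,
    stringsAsFactors = FALSE, row.names = NULL
  )
  class(out) <- c("gpro_tokens", "data.frame")
  out
}

#' Sub-tokenize a whole token sequence
#'
#' @param tokens a `gpro_tokens` data frame.
#' @return A `gpro_tokens` data frame of sub-tokens, order preserved, with a
#'   `parent` column giving the row index of the source token.
#' @export
sub_tokenize_all <- function(tokens) {
  if (nrow(tokens) == 0L) {
    out <- empty_tokens()
    out$parent <- integer(0)
    return(out)
  }
  pieces <- lapply(seq_len(nrow(tokens)), function(i) {
    p <- sub_tokenize(tokens[i, , drop = FALSE])
    p$parent <- i
    p
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("gpro_tokens", "data.frame")
  out
}

#' Deterministic regex-based POS/chunk fallback tagger
#'
#' A lightweight stand-in for a full tagger: closed-class words and simple
#' suffix rules map to Penn-style tags; everything with no alphanumeric
#' character is tagged as itself with chunk `"O"`, all other tokens fall in
#' a noun-phrase chunk.
#'
#' @param tokens a `gpro_tokens` data frame (pos/chunk columns ignored).
#' @return `list(pos = character, chunk = character)`.
#' @export
regex_tagger <- function(tokens) {
  w <- tokens$surface
  lw <- tolower(w)
  pos <- rep("NN", length(w))
  pos[grepl("^-?[0-9][0-9.,]*$", w)] <- "CD"
  pos[lw %in% c("and", "or", "but")] <- "CC"
  pos[lw %in% c("in", "of", "on", "by", "with", "for", "to", "at",
                "from", "into", "via")] <- "IN"
  pos[lw %in% c("the", "a", "an", "this", "that", "these", "those")] <- "DT"
  pos[lw %in% c("is", "are", "was", "were", "be", "been")] <- "VB"
  pos[grepl("[a-z]ly$", lw)] <- "RB"
  pos[grepl("[a-z]ing$", lw)] <- "VBG"
  pos[grepl("[a-z]ed$", lw)] <- "VBN"
  is_punct <- !grepl("[A-Za-z0-9]", w)
  pos[is_punct] <- w[is_punct]
  chunk <- ifelse(is_punct, "O", "I-NP")
  list(pos = pos, chunk = chunk)
}

#' Identity tagger (no POS/chunk information)
#'
#' @param tokens a `gpro_tokens` data frame.
#' @return `list(pos, chunk)` with constant `"X"` tags.
#' @export
identity_tagger <- function(tokens) {
  list(pos = rep("X", nrow(tokens)), chunk = rep("X", nrow(tokens)))
}
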