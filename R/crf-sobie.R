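# SOBIE tag scheme: nine labels, {S,B,I,E} x {GPRO_TYPE_1, GPRO_TYPE_2}
# plus O. B/I/E mark beginning/inner/end of a multi-token mention, S a
# singleton, O everything else.

GPRO_TYPES <- c("GPRO_TYPE_1", "GPRO_TYPE_2")

#' The nine SOBIE labels
#' @return Character vector of the label set, `O` first.
#' @export
sobie_labels <- function() {
  c("O", as.vector(outer(c("B-", "I-", "E-", "S-"), GPRO_TYPES, paste0)))
}

#' Encode token-aligned mentions as SOBIE labels
#'
#' Mentions are snapped outward to token boundaries: every token whose span
#' overlaps the mention belongs to it. Overlapping mentions are an error.
#'
#' @param tokens `gpro_tokens` of one sentence (typically sub-tokens).
#' @param ments `gpro_mentions` whose offsets live in the same section as
#'   `tokens`; mentions not overlapping the token range are ignored.
#' @return Character vector of SOBIE labels, one per token.
#' @export
encode_sobie <- function(tokens, ments) {
  n <- nrow(tokens)
  out <- rep("O", n)
  if (n == 0L || nrow(ments) == 0L) return(out)
  claimed <- rep(FALSE, n)
  for (i in seq_len(nrow(ments))) {
    idx <- which(tokens$start < ments$end[i] & tokens$end > ments$start[i])
    if (length(idx) == 0L) next
    if (any(claimed[idx])) {
      stop(sprintf("overlapping mentions at [%d,%d): SOBIE encoding requires non-overlapping mentions",
                   ments$start[i], ments$end[i]))
    }
    claimed[idx] <- TRUE
    ty <- ments$etype[i]
    if (!ty %in% GPRO_TYPES) {
      stop(sprintf("cannot SOBIE-encode etype '%s'", ty))
    }
    if (length(idx) == 1L) {
      out[idx] <- paste0("S-", ty)
    } else {
      out[idx[1L]] <- paste0("B-", ty)
      out[idx[length(idx)]] <- paste0("E-", ty)
      if (length(idx) > 2L) out[idx[-c(1L, length(idx))]] <- paste0("I-", ty)
    }
  }
  out
}

sobie_split <- function(lab) {
  pos <- sub("-.*$", "", lab)
  ty <- sub("^[BIES]-", "", lab)
  ty[lab == "O"] <- NA_character_
  list(pos = pos, type = ty)
}

#' Decode SOBIE labels into mentions
#'
#' Tolerates ill-formed model output with a fixed repair rule: a leading `I`
#' (or an `I`/`E` whose type disagrees with the open run) starts a new
#' mention as if it were `B`; an unterminated `B`/`I` run is closed at its
#' last in-type token.
#'
#' @param labels character vector of SOBIE labels.
#' @param tokens `gpro_tokens` aligned with `labels`.
#' @param doc_id,section mention identity fields.
#' @param text section text for exact mention slices; when `NULL` the
#'   surfaces are joined with single spaces.
#' @return A `gpro_mentions` data frame.
#' @export
decode_sobie <- function(labels, tokens, doc_id = "doc", section = "abstract",
                         text = NULL) {
  n <- length(labels)
  stopifnot(n == nrow(tokens))
  runs <- list()
  open_start <- NA_integer_
  open_type <- NA_character_
  close_run <- function(endi) {
    if (!is.na(open_start)) {
      runs[[length(runs) + 1L]] <<- c(open_start, endi, open_type)
    }
    open_start <<- NA_integer_
    open_type <<- NA_character_
  }
  sp <- sobie_split(labels)
  for (i in seq_len(n)) {
    p <- sp$pos[i]; ty <- sp$type[i]
    if (p == "O") {
      close_run(i - 1L)
    } else if (p == "S") {
      close_run(i - 1L)
      runs[[length(runs) + 1L]] <- c(i, i, ty)
    } else if (p == "B") {
      close_run(i - 1L)
      open_start <- i; open_type <- ty
    } else if (p == "I") {
      if (is.na(open_start) || open_type != ty) {   # repair: treat as B
        close_run(i - 1L)
        open_start <- i; open_type <- ty
      }
    } else if (p == "E") {
      if (is.na(open_start) || open_type != ty) {   # repair: lone E = B,E
        close_run(i - 1L)
        open_start <- i; open_type <- ty
      }
      close_run(i)
    }
  }
  close_run(n)
  if (length(runs) == 0L) return(mentions())
  st <- vapply(runs, function(r) tokens$start[as.integer(r[1L])], 0L)
  en <- vapply(runs, function(r) tokens$end[as.integer(r[2L])], 0L)
  ty <- vapply(runs, function(r) r[3L], "")
  txt <- if (!is.null(text)) slice_text(text, st, en) else
    vapply(runs, function(r) {
      paste(tokens$surface[as.integer(r[1L]):as.integer(r[2L])], collapse = " ")
    }, "")
  mentions(doc_id, section, st, en, txt, ty)
}

word_shape <- function(w) {
  chartr(paste(c(letters, LETTERS, 0:9), collapse = ""),
         paste(c(strrep("a", 26), strrep("A", 26), strrep("0", 10)), collapse = ""),
         w)
}

brief_shape <- function(shape) {
  gsub("(.)\\1+", "\\1", shape)
}

spba_sobie_flag <- function(tokens, spba_ments) {
  n <- nrow(tokens)
  out <- rep("O", n)
  if (n == 0L || is.null(spba_ments) || nrow(spba_ments) == 0L) return(out)
  for (i in seq_len(nrow(spba_ments))) {
    idx <- which(tokens$start < spba_ments$end[i] & tokens$end > spba_ments$start[i])
    if (length(idx) == 0L) next
    if (length(idx) == 1L) out[idx] <- "S"
    else {
      out[idx[1L]] <- "B"
      out[idx[length(idx)]] <- "E"
      if (length(idx) > 2L) out[idx[-c(1L, length(idx))]] <- "I"
    }
  }
  out
}

#' Extract CRF feature strings for every position of a sentence
#'
#' Per sub-token: digit-normalized lowercased word, POS, chunk, prefixes and
#' suffixes of lengths 2-4, orthographic flags (initial capital, all caps,
#' contains digit, contains hyphen, Greek-letter word, punctuation), word
#' shape and collapsed shape, and the SPBA flag (SOBIE-style position of the
#' sub-token inside any overlapping SPBA `GENE` mention, `"O"` otherwise).
#' Word, POS and SPBA features are repeated for a window of two positions
#' either side with BOS/EOS padding.
#'
#' @param tokens `gpro_tokens` of one sentence (sub-tokens).
#' @param spba_ments optional `gpro_mentions` of SPBA predictions overlapping
#'   this sentence; `NULL` disables the SPBA feature group.
#' @param use_spba include the SPBA feature group (flag exists so ablation
#'   does not disturb the other groups).
#' @return A list of character vectors, one per position.
#' @export
extract_features <- function(tokens, spba_ments = NULL, use_spba = TRUE) {
  n <- nrow(tokens)
  if (n == 0L) return(list())
  w <- tokens$surface
  norm <- gsub("[0-9]", "0", tolower(w))
  shape <- word_shape(w)
  spba <- spba_sobie_flag(tokens, spba_ments)
  pad <- function(x, off, fill) {
    idx <- seq_len(n) + off
    out <- rep(fill, n)
    ok <- idx >= 1L & idx <= n
    out[ok] <- x[idx[ok]]
    out
  }
  base <- vector("list", n)
  for (i in seq_len(n)) {
    f <- c(paste0("w0=", norm[i]),
           paste0("p0=", tokens$pos[i]),
           paste0("c0=", tokens$chunk[i]),
           paste0("shape=", shape[i]),
           paste0("bshape=", brief_shape(shape[i])))
    nc <- nchar(w[i])
    for (l in 2:4) {
      if (nc >= l) {
        f <- c(f, paste0("pre", l, "=", substr(norm[i], 1L, l)),
               paste0("suf", l, "=", substr(norm[i], nc - l + 1L, nc)))
      }
    }
    if (grepl("^[A-Z]", w[i])) f <- c(f, "o:init_cap")
    if (grepl("^[A-Z]{2,}$", w[i])) f <- c(f, "o:all_caps")
    if (grepl("[0-9]", w[i])) f <- c(f, "o:has_digit")
    if (grepl("-", w[i], fixed = TRUE)) f <- c(f, "o:has_hyphen")
    if (tolower(w[i]) %in% GREEK_WORDS) f <- c(f, "o:greek")
    if (!grepl("[A-Za-z0-9]", w[i])) f <- c(f, "o:punct")
    base[[i]] <- f
  }
  for (off in c(-2L, -1L, 1L, 2L)) {
    wo <- pad(norm, off, if (off < 0L) "<BOS>" else "<EOS>")
    po <- pad(tokens$pos, off, if (off < 0L) "<BOS>" else "<EOS>")
    for (i in seq_len(n)) {
      base[[i]] <- c(base[[i]],
                     sprintf("w%+d=%s", off, wo[i]),
                     sprintf("p%+d=%s", off, po[i]))
    }
  }
  if (use_spba) {
    for (i in seq_len(n)) base[[i]] <- c(base[[i]], paste0("spba0=", spba[i]))
    for (off in c(-2L, -1L, 1L, 2L)) {
      so <- pad(spba, off, "O")
      for (i in seq_len(n)) {
        base[[i]] <- c(base[[i]], sprintf("spba%+d=%s", off, so[i]))
      }
    }
  }
  base
}
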