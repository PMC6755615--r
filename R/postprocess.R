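# Post-processing: identifier mapping (type assignment), document-level
# tag consistency, the annotation-standard span rules around
# "receptor"/"protein", and blacklist filtering.

#' Normalize an entity name for dictionary lookup
#'
#' Lowercase, remove all non-alphanumeric characters, then strip a single
#' trailing `"s"` (in that order; a double `"ss"` ending is left alone so
#' the map is idempotent).
#'
#' @param name character vector.
#' @return Normalized character vector.
#' @export
normalize_name <- function(name) {
  x <- tolower(name)
  x <- gsub("[^a-z0-9]", "", x)
  sub("(?<=[a-z0-9])(?<!s)s$", "", x, perl = TRUE)
}

#' Build an identifier-mapping table
#'
#' @param names character vector of entity names.
#' @param ids list (parallel to `names`) of character vectors of database
#'   ids for each name.
#' @param homolog named character vector mapping ids to human ids; ids
#'   absent from it map to themselves, and human ids map to themselves
#'   (idempotent).
#' @return An object of class `id_table`.
#' @export
id_table <- function(names = character(0), ids = list(),
                     homolog = character(0)) {
  stopifnot(length(names) == length(ids))
  key <- normalize_name(names)
  tab <- split(unlist(lapply(seq_along(ids), function(i) {
    as.character(ids[[i]])
  })), rep(key, lengths(ids)))
  tab <- lapply(tab, unique)
  structure(list(map = tab, homolog = homolog), class = "id_table")
}

#' Read an id table and homolog table from TSV files
#'
#' Id table format: `name <TAB> id` (one id per row, repeated names
#' accumulate). Homolog format: `id <TAB> human_id`.
#'
#' @param id_path,homolog_path file paths; `homolog_path` may be `NULL`.
#' @return An `id_table`.
#' @export
read_id_table <- function(id_path, homolog_path = NULL) {
  lex <- read_lexicon(id_path)   # same 2-column TSV shape
  hom <- character(0)
  if (!is.null(homolog_path)) {
    h <- read_lexicon(homolog_path)
    hom <- setNames(h$class, h$term)
  }
  nm <- unique(lex$term)
  id_table(nm, lapply(nm, function(x) lex$class[lex$term == x]), hom)
}

collapse_homolog <- function(ids, homolog) {
  if (length(ids) == 0L) return(ids)
  mapped <- homolog[ids]
  mapped[is.na(mapped)] <- ids[is.na(mapped)]
  unique(unname(mapped))
}

lookup_ids <- function(table, name) {
  ids <- table$map[[normalize_name(name)]]
  if (is.null(ids)) ids <- character(0)
  collapse_homolog(ids, table$homolog)
}

#' Assign GPRO types by identifier mapping
#'
#' After collapsing homolog ids to human ids, a mention whose surface maps
#' to exactly one database id becomes `GPRO_TYPE_1`; any other id count
#' (zero, or two and more) makes it `GPRO_TYPE_2`. Spans are unchanged.
#' Idempotent.
#'
#' @param ments a `gpro_mentions` data frame.
#' @param table an `id_table`.
#' @return The mentions with re-assigned `etype`.
#' @export
assign_type_by_id <- function(ments, table) {
  if (nrow(ments) == 0L) return(ments)
  nids <- vapply(ments$text, function(x) length(lookup_ids(table, x)), 0L)
  ments$etype <- ifelse(nids == 1L, "GPRO_TYPE_1", "GPRO_TYPE_2")
  ments
}

token_boundary_occurrences <- function(text, surface) {
  if (!nzchar(surface)) return(integer(0))
  hits <- gregexpr(surface, text, fixed = TRUE)[[1L]]
  if (hits[1L] == -1L) return(integer(0))
  starts <- as.integer(hits) - 1L
  ends <- starts + nchar(surface)
  ok <- vapply(seq_along(starts), function(i) {
    before <- if (starts[i] > 0L) substr(text, starts[i], starts[i]) else ""
    after <- if (ends[i] < nchar(text)) substr(text, ends[i] + 1L, ends[i] + 1L) else ""
    !grepl("[A-Za-z0-9]", before) && !grepl("[A-Za-z0-9]", after)
  }, TRUE)
  starts[ok]
}

#' Detect full-form / abbreviation pairs in a text
#'
#' Parenthesis heuristic: for every parenthesized candidate of 1-10
#' characters containing a letter, the shortest immediately-preceding word
#' window whose letters contain the abbreviation's letters in order
#' (case-insensitive subsequence test) is taken as the full form.
#'
#' @param text section text.
#' @return Data frame with columns `full`, `abbrev`, `full_start`,
#'   `full_end`, `abbrev_start`, `abbrev_end` (0-based, half-open).
#' @export
detect_abbrev_pairs <- function(text) {
  out <- data.frame(full = character(0), abbrev = character(0),
                    full_start = integer(0), full_end = integer(0),
                    abbrev_start = integer(0), abbrev_end = integer(0),
                    stringsAsFactors = FALSE)
  m <- gregexpr("\\(([^()]{1,10})\\)", text, perl = TRUE)[[1L]]
  if (m[1L] == -1L) return(out)
  toks <- tokenize(text, tagger = identity_tagger)
  is_subseq <- function(needle, hay) {
    n <- strsplit(tolower(needle), "")[[1L]]
    n <- n[grepl("[a-z]", n)]
    h <- strsplit(tolower(hay), "")[[1L]]
    i <- 1L
    for (ch in h) {
      if (i <= length(n) && ch == n[i]) i <- i + 1L
    }
    i > length(n)
  }
  for (k in seq_along(m)) {
    a_start <- as.integer(m[k])           # 1-based position of "("
    a_len <- attr(m, "match.length")[k]
    abbrev <- substr(text, a_start + 1L, a_start + a_len - 2L)
    if (!grepl("[A-Za-z]", abbrev)) next
    paren_open0 <- a_start - 1L           # 0-based offset of "("
    before <- which(toks$end <= paren_open0 &
                      grepl("[A-Za-z0-9]", toks$surface))
    if (length(before) == 0L) next
    max_words <- min(length(before), nchar(abbrev) + 5L)
    found <- NULL
    for (w in seq_len(max_words)) {
      idx <- tail(before, w)
      cand <- slice_text(text, toks$start[idx[1L]], toks$end[idx[length(idx)]])
      if (is_subseq(abbrev, cand)) { found <- idx; break }
    }
    if (is.null(found)) next
    out <- rbind(out, data.frame(
      full = slice_text(text, toks$start[found[1L]], toks$end[found[length(found)]]),
      abbrev = abbrev,
      full_start = toks$start[found[1L]],
      full_end = toks$end[found[length(found)]],
      abbrev_start = paren_open0 + 1L,
      abbrev_end = paren_open0 + 1L + nchar(abbrev),
      stringsAsFactors = FALSE))
  }
  out
}

section_text <- function(corp, doc_id, section) {
  i <- match(doc_id, corp$doc_id)
  if (is.na(i)) stop(sprintf("unknown doc_id '%s'", doc_id))
  if (section == "title") corp$title[i] else corp$abstract[i]
}

#' Enforce document-level tag consistency
#'
#' Every untagged, token-boundary-aligned occurrence of a recognized mention
#' surface (or the paired abbreviation/full form of one) within the same
#' document is added with the recognized type. Additions are resolved
#' leftmost-longest and never overlap existing mentions, which are never
#' modified.
#'
#' @param corp a `gpro_corpus`.
#' @param ments predicted mentions.
#' @return Augmented `gpro_mentions`, sorted by document, section, start.
#' @export
enforce_consistency <- function(corp, ments) {
  if (nrow(ments) == 0L) return(ments)
  added <- list()
  for (d in unique(ments$doc_id)) {
    dm <- ments[ments$doc_id == d, , drop = FALSE]
    # surface -> type of recognized mentions, plus abbreviation partners
    surfaces <- unique(data.frame(text = dm$text, etype = dm$etype,
                                  stringsAsFactors = FALSE))
    for (sec in SECTIONS) {
      txt <- section_text(corp, d, sec)
      if (!nzchar(txt)) next
      pairs <- detect_abbrev_pairs(txt)
      if (nrow(pairs) > 0L) {
        for (i in seq_len(nrow(pairs))) {
          hit_full <- surfaces$text == pairs$full[i]
          hit_abbr <- surfaces$text == pairs$abbrev[i]
          if (any(hit_full) && !any(surfaces$text == pairs$abbrev[i])) {
            surfaces <- rbind(surfaces, data.frame(
              text = pairs$abbrev[i], etype = surfaces$etype[hit_full][1L],
              stringsAsFactors = FALSE))
          } else if (any(hit_abbr) && !any(surfaces$text == pairs$full[i])) {
            surfaces <- rbind(surfaces, data.frame(
              text = pairs$full[i], etype = surfaces$etype[hit_abbr][1L],
              stringsAsFactors = FALSE))
          }
        }
      }
    }
    for (sec in SECTIONS) {
      txt <- section_text(corp, d, sec)
      if (!nzchar(txt)) next
      covered <- dm[dm$section == sec, , drop = FALSE]
      # longest surfaces first: leftmost-longest among additions
      ord <- order(-nchar(surfaces$text))
      cand <- list()
      for (i in ord) {
        for (s0 in token_boundary_occurrences(txt, surfaces$text[i])) {
          cand[[length(cand) + 1L]] <- c(s0, s0 + nchar(surfaces$text[i]), i)
        }
      }
      if (length(cand) == 0L) next
      cl <- do.call(rbind, cand)
      cl <- cl[order(-(cl[, 2L] - cl[, 1L]), cl[, 1L]), , drop = FALSE]
      for (r in seq_len(nrow(cl))) {
        s0 <- cl[r, 1L]; e0 <- cl[r, 2L]; i <- cl[r, 3L]
        overlaps <- any(covered$start < e0 & covered$end > s0)
        if (overlaps) next
        newm <- mentions(d, sec, s0, e0, surfaces$text[i], surfaces$etype[i])
        covered <- rbind(covered, newm)
        added[[length(added) + 1L]] <- newm
      }
    }
  }
  out <- ments
  if (length(added) > 0L) {
    out <- rbind(ments, do.call(rbind, added))
    class(out) <- c("gpro_mentions", "data.frame")
  }
  out[order(out$doc_id, out$section, out$start), , drop = FALSE]
}

next_word <- function(toks, after_end) {
  i <- which(toks$start >= after_end & grepl("[A-Za-z0-9]", toks$surface))
  if (length(i) == 0L) return(NULL)
  toks[min(i), , drop = FALSE]
}

#' Merge "full name (ABBR) receptor" constructions into one mention
#'
#' When a recognized full-form mention is immediately followed by its
#' parenthesized recognized abbreviation and then the keyword `"receptor"`,
#' the pair and the keyword merge into a single mention whose span extends
#' to the end of the keyword. The plural `"receptors"` is accepted when
#' `accept_plural` is `TRUE`.
#'
#' @param corp a `gpro_corpus`.
#' @param ments predicted mentions.
#' @param accept_plural also merge before `"receptors"`.
#' @return Updated `gpro_mentions`.
#' @export
apply_full_abbrev_receptor_rule <- function(corp, ments, accept_plural = TRUE) {
  if (nrow(ments) == 0L) return(ments)
  keywords <- c("receptor", if (accept_plural) "receptors")
  drop <- rep(FALSE, nrow(ments))
  for (d in unique(ments$doc_id)) {
    for (sec in SECTIONS) {
      sel <- which(ments$doc_id == d & ments$section == sec)
      if (length(sel) < 2L) next
      txt <- section_text(corp, d, sec)
      pairs <- detect_abbrev_pairs(txt)
      if (nrow(pairs) == 0L) next
      toks <- tokenize(txt, tagger = identity_tagger)
      for (i in seq_len(nrow(pairs))) {
        fi <- sel[!drop[sel] & ments$start[sel] == pairs$full_start[i] &
                    ments$end[sel] == pairs$full_end[i]]
        ai <- sel[!drop[sel] & ments$start[sel] == pairs$abbrev_start[i] &
                    ments$end[sel] == pairs$abbrev_end[i]]
        if (length(fi) != 1L || length(ai) != 1L) next
        close_paren_end <- pairs$abbrev_end[i] + 1L
        nw <- next_word(toks, close_paren_end)
        if (is.null(nw) || !(tolower(nw$surface) %in% keywords)) next
        ments$end[fi] <- nw$end
        ments$text[fi] <- slice_text(txt, ments$start[fi], ments$end[fi])
        drop[ai] <- TRUE
      }
    }
  }
  out <- ments[!drop, , drop = FALSE]
  class(out) <- c("gpro_mentions", "data.frame")
  out
}

#' Apply the short-name span rules around the keyword "protein"
#'
#' Rule 1: a recognized two-token mention ending in `"protein"` whose first
#' token is at least 3 characters long loses the trailing `"protein"`.
#' Rule 2: a recognized single-word mention shorter than 3 characters that
#' is immediately followed by the word `"protein"` absorbs it.
#'
#' @param corp a `gpro_corpus`.
#' @param ments predicted mentions.
#' @return Updated `gpro_mentions`.
#' @export
apply_short_name_rules <- function(corp, ments) {
  if (nrow(ments) == 0L) return(ments)
  for (i in seq_len(nrow(ments))) {
    txt <- section_text(corp, ments$doc_id[i], ments$section[i])
    mtoks <- tokenize(ments$text[i], tagger = identity_tagger)
    if (nrow(mtoks) == 2L && tolower(mtoks$surface[2L]) == "protein" &&
        nchar(mtoks$surface[1L]) >= 3L) {
      ments$end[i] <- ments$start[i] + mtoks$end[1L]
      ments$text[i] <- slice_text(txt, ments$start[i], ments$end[i])
    } else if (nrow(mtoks) == 1L && nchar(mtoks$surface[1L]) < 3L) {
      toks <- tokenize(txt, tagger = identity_tagger)
      nw <- next_word(toks, ments$end[i])
      if (!is.null(nw) && tolower(nw$surface) == "protein") {
        ments$end[i] <- nw$end
        ments$text[i] <- slice_text(txt, ments$start[i], ments$end[i])
      }
    }
  }
  ments
}

#' Remove mentions whose normalized surface is blacklisted
#'
#' @param ments predicted mentions.
#' @param blacklist character vector of terms (chemical/drug names);
#'   membership is tested on [normalize_name()] of both sides.
#' @return Filtered `gpro_mentions`.
#' @export
filter_blacklist <- function(ments, blacklist) {
  if (nrow(ments) == 0L || length(blacklist) == 0L) return(ments)
  bl <- unique(normalize_name(blacklist))
  out <- ments[!(normalize_name(ments$text) %in% bl), , drop = FALSE]
  class(out) <- c("gpro_mentions", "data.frame")
  out
}

#' Read a blacklist file (one term per line)
#' @param path file path.
#' @return Character vector of terms.
#' @export
read_blacklist <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines[nzchar(lines)]
}

#' Full post-processing pipeline
#'
#' Applies, in order: identifier-based type assignment, document tag
#' consistency, the annotation-standard span rules (receptor merge, then
#' short-name rules), and blacklist filtering. Each step can be disabled;
#' with everything disabled the input is returned unchanged.
#'
#' @param corp a `gpro_corpus`.
#' @param ments predicted mentions.
#' @param table optional `id_table` (`NULL` skips id mapping).
#' @param blacklist optional character vector (`NULL` skips filtering).
#' @param id_mapping,consistency,annotation_rules,blacklist_filter step
#'   switches.
#' @param accept_plural_receptor see [apply_full_abbrev_receptor_rule()].
#' @return Post-processed `gpro_mentions`.
#' @export
postprocess <- function(corp, ments, table = NULL, blacklist = NULL,
                        id_mapping = TRUE, consistency = TRUE,
                        annotation_rules = TRUE, blacklist_filter = TRUE,
                        accept_plural_receptor = TRUE) {
  out <- ments
  if (id_mapping && !is.null(table)) out <- assign_type_by_id(out, table)
  if (consistency) out <- enforce_consistency(corp, out)
  if (annotation_rules) {
    out <- apply_full_abbrev_receptor_rule(corp, out, accept_plural_receptor)
    out <- apply_short_name_rules(corp, out)
  }
  if (blacklist_filter && !is.null(blacklist)) {
    out <- filter_blacklist(out, blacklist)
  }
  validate_mentions(out, corp)
  out
}
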