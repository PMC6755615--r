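# Identifier mapping, tag consistency, annotation-standard span rules and
# blacklist filtering.

test_that("name normalization lowercases, strips symbols and a plural s", {
  expect_equal(normalize_name("EGFRs"), "egfr")
  expect_equal(normalize_name("p53"), "p53")
  expect_equal(normalize_name("TNF-alpha"), "tnfalpha")
  # idempotent
  x <- c("EGFRs", "p53", "TNF-alpha", "Ras", "class")
  expect_equal(normalize_name(normalize_name(x)), normalize_name(x))
})

homolog_fixture <- function() {
  # "zetor" carries a mouse id and a human id; the homolog table collapses
  # both onto the human record
  id_table(names = c("zetor", "bamol", "unique1"),
           ids = list(c("H001", "M001"), c("H002", "H003"), "H004"),
           homolog = c(M001 = "H001", H001 = "H001"))
}

test_that("id mapping assigns Type 1 exactly on unique ids", {
  tab <- homolog_fixture()
  m <- mentions(rep("d", 4), "abstract", c(0L, 5L, 10L, 15L),
                c(3L, 8L, 13L, 18L),
                c("unique1", "bamol", "nothere", "zetor"), "GPRO_TYPE_1")
  out <- assign_type_by_id(m, tab)
  expect_equal(out$etype[out$text == "unique1"], "GPRO_TYPE_1")  # one id
  expect_equal(out$etype[out$text == "bamol"], "GPRO_TYPE_2")    # two ids
  expect_equal(out$etype[out$text == "nothere"], "GPRO_TYPE_2")  # zero ids
  # two ids collapsing to one human id -> Type 1
  expect_equal(out$etype[out$text == "zetor"], "GPRO_TYPE_1")
  # spans untouched, idempotent
  expect_equal(out[, c("start", "end", "text")], m[, c("start", "end", "text")])
  expect_equal(assign_type_by_id(out, tab), out)
})

test_that("id table lookups normalize names and homolog mapping is idempotent", {
  tab <- homolog_fixture()
  expect_equal(spbacrf:::lookup_ids(tab, "Zetors"), "H001")
  expect_equal(spbacrf:::collapse_homolog("H001", tab$homolog), "H001")
})

test_that("tag consistency adds untagged identical occurrences", {
  corp <- corpus("d1", abstract = "TNF rises early. Later TNF falls. TNFx stays.")
  first <- regexpr("TNF", corp$abstract, fixed = TRUE) - 1L
  m <- mentions("d1", "abstract", first, first + 3L, "TNF", "GPRO_TYPE_1")
  out <- enforce_consistency(corp, m)
  expect_equal(nrow(out), 2L)           # "TNFx" is not token-boundary aligned
  expect_equal(unique(out$text), "TNF")
  expect_equal(unique(out$etype), "GPRO_TYPE_1")
  validate_mentions(out, corp)

  # no recognized mentions: unchanged
  expect_equal(nrow(enforce_consistency(corp, mentions())), 0L)

  # a candidate overlapping an existing mention is skipped
  corp2 <- corpus("d2", abstract = "ABC binds. The ABC DEF complex binds ABC DEF.")
  s1 <- regexpr("ABC DEF complex", corp2$abstract, fixed = TRUE) - 1L
  m2 <- rbind(
    mentions("d2", "abstract", 0L, 3L, "ABC", "GPRO_TYPE_1"),
    mentions("d2", "abstract", s1, s1 + 7L, "ABC DEF", "GPRO_TYPE_2"))
  class(m2) <- c("gpro_mentions", "data.frame")
  out2 <- enforce_consistency(corp2, m2)
  # additions resolve leftmost-longest: trailing "ABC DEF" added as one
  # mention (not as a nested "ABC"), existing mentions untouched
  expect_true(all(c("ABC", "ABC DEF") %in% out2$text))
  trailing <- out2[out2$start >= nchar(corp2$abstract) - 10L, ]
  expect_equal(trailing$text, "ABC DEF")
  expect_equal(trailing$etype, "GPRO_TYPE_2")
  check_overlap <- out2[order(out2$start), ]
  expect_true(all(check_overlap$start[-1L] >= check_overlap$end[-nrow(check_overlap)]))
})

test_that("abbreviation pairs come from the parenthesis subsequence heuristic", {
  p <- detect_abbrev_pairs("the epidermal growth factor (EGF) receptor")
  expect_equal(p$full, "epidermal growth factor")
  expect_equal(p$abbrev, "EGF")

  expect_equal(nrow(detect_abbrev_pairs("as shown in (2005) by")), 0L)

  p2 <- detect_abbrev_pairs("tumor necrosis factor (TNF) signaling")
  expect_equal(p2$full, "tumor necrosis factor")
  expect_equal(p2$abbrev, "TNF")
})

test_that("the receptor rule merges full name, abbreviation and keyword", {
  rc <- plant_rule_cases()
  corp <- rc$corpus
  pre <- rc$pre[rc$pre$doc_id == "R1", ]
  class(pre) <- c("gpro_mentions", "data.frame")
  out <- apply_full_abbrev_receptor_rule(corp, pre)
  expect_equal(nrow(out), 1L)
  expect_equal(out$text, "epidermal growth factor (EGF) receptor")
  validate_mentions(out, corp)

  # without the trailing keyword nothing merges
  corp2 <- corpus("x", abstract = "the epidermal growth factor (EGF) pathway")
  s <- regexpr("epidermal", corp2$abstract, fixed = TRUE) - 1L
  a <- regexpr("EGF", corp2$abstract, fixed = TRUE) - 1L
  m <- rbind(mentions("x", "abstract", s, s + 23L, "epidermal growth factor",
                      "GPRO_TYPE_1"),
             mentions("x", "abstract", a, a + 3L, "EGF", "GPRO_TYPE_1"))
  class(m) <- c("gpro_mentions", "data.frame")
  expect_equal(apply_full_abbrev_receptor_rule(corp2, m)$text, m$text)

  # plural keyword accepted by default, refused when disabled
  corp3 <- corpus("y", abstract = "the epidermal growth factor (EGF) receptors bind")
  m3 <- m
  m3$doc_id <- "y"
  validate_mentions(m3, corp3)
  merged <- apply_full_abbrev_receptor_rule(corp3, m3)
  expect_equal(merged$text, "epidermal growth factor (EGF) receptors")
  expect_equal(nrow(apply_full_abbrev_receptor_rule(corp3, m3,
                                                    accept_plural = FALSE)), 2L)
})

test_that("short-name rules trim or absorb the keyword protein", {
  rc <- plant_rule_cases()
  corp <- rc$corpus
  m2 <- rc$pre[rc$pre$doc_id == "R2", ]; class(m2) <- c("gpro_mentions", "data.frame")
  out2 <- apply_short_name_rules(corp, m2)
  expect_equal(out2$text, "p53")

  m3 <- rc$pre[rc$pre$doc_id == "R3", ]; class(m3) <- c("gpro_mentions", "data.frame")
  out3 <- apply_short_name_rules(corp, m3)
  expect_equal(out3$text, "AR protein")

  # a 4-character name followed by "protein" stays as is
  corp4 <- corpus("z", abstract = "the ABCD protein binds")
  m4 <- mentions("z", "abstract", 4L, 8L, "ABCD", "GPRO_TYPE_1")
  expect_equal(apply_short_name_rules(corp4, m4)$text, "ABCD")
})

test_that("blacklist filtering removes normalized matches", {
  corp <- corpus("d", abstract = "Glucose rises while ZOR4 falls.")
  m <- rbind(mentions("d", "abstract", 0L, 7L, "Glucose", "GPRO_TYPE_2"),
             mentions("d", "abstract", 20L, 24L, "ZOR4", "GPRO_TYPE_1"))
  class(m) <- c("gpro_mentions", "data.frame")
  out <- filter_blacklist(m, c("glucose", "sodium"))
  expect_equal(out$text, "ZOR4")
  expect_equal(filter_blacklist(m, character(0)), m)
})

test_that("the pipeline with every step disabled is the identity", {
  rc <- plant_rule_cases()
  out <- postprocess(rc$corpus, rc$pre, table = homolog_fixture(),
                     blacklist = "glucose", id_mapping = FALSE,
                     consistency = FALSE, annotation_rules = FALSE,
                     blacklist_filter = FALSE)
  expect_equal(out, rc$pre)
})

test_that("the full pipeline reproduces the expected rule-case annotations", {
  rc <- plant_rule_cases()
  out <- postprocess(rc$corpus, rc$pre, id_mapping = FALSE)
  a <- out[order(out$doc_id, out$start), ]
  b <- rc$expected[order(rc$expected$doc_id, rc$expected$start), ]
  rownames(a) <- rownames(b) <- NULL
  expect_equal(a, b)
  # never overlapping, offsets intact
  validate_mentions(out, rc$corpus)
  key <- paste(a$doc_id, a$section)
  for (k in unique(key)) {
    g <- a[key == k, ]
    expect_true(all(g$start[-1L] >= g$end[-nrow(g)]))
  }
})
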