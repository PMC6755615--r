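---
title: "Methods: dictionary patterns, a SOBIE CRF, and span rules for GPRO recognition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dictionary patterns, a SOBIE CRF, and span rules for GPRO recognition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains what `spbacrf` computes, the assumptions behind each
stage, the parameters that matter, and the choices made where the design
was genuinely open.

## The recognition problem

Given a patent-style abstract, the system must find the character spans of
gene- and protein-related object (GPRO) mentions and decide for each
whether it can be linked to a unique biological database record (Type 1)
or not (Type 2). Span conventions are tied to database records rather than
to syntax — *"A2A receptors"* is one Type 1 mention — so a purely lexical
tagger and a purely dictionary-based matcher both fail in characteristic
ways. The package combines them: an interpretable dictionary-and-pattern
recognizer (SPBA) supplies features to a discriminative sequence tagger
(CRF), and rule-based post-processing repairs spans and types.

## Concept knowledge base and labeling

A CKB maps terms to concept classes in four groups: *Symbol* classes
(`GeneSymbol`, `CellLineSymbol`, `CellTypeSymbol`, `ChromosomeSymbol`),
*NEKeyword* classes (`ProteinKeyword`, `DNAKeyword`, `RNAKeyword`,
`CellKeyword`, `CellLineKeyword`, plus `Enzyme`), *Attribute* classes
(`Taxonomy`, `Chemical`, `Disease`, `BiologicalProcess`, `Morphology`,
`OrganTissue`, `Structure`, plus `Unit`) and *Others* (`Conjunction`,
`Preposition`, `Specifier`). `Unit` and `Enzyme` are admitted because
induced patterns use them even though no lexicon source is prescribed for
them; in practice they are supplied as ordinary lexicon files. Two classes
ship as regular expressions rather than term lists: chromosome loci
(`11p15`, `14q32.1`) and specifiers (Greek letters, Roman numerals, short
alphanumeric qualifiers like `2A`); both defaults are overridable.

Labeling is greedy leftmost-longest over whitespace-delimited token
phrases; regexes only apply to single tokens the lexicon leaves unlabeled,
and labels never overlap. Two policies had to be fixed where no convention
exists:

* **Case.** Terms of ≥ 4 characters match case-insensitively; shorter
  terms match exactly. This protects short symbols (`AR`, `MAP`) from
  colliding with ordinary words while letting `kinase`/`Kinase` unify.
* **Ambiguity.** When one term carries several classes, the emitted class
  follows the fixed priority Symbol > NEKeyword > Attribute > Others, then
  alphabetical order — symbols are the rarest and most informative signal,
  so they win.

## Pattern induction and approximate matching

For each gold mention, all non-overlapping labelings of its tokens are
enumerated; the one covering the most words (highest *labeled ratio* =
labeled words / total words) wins, ties resolved by the class priority.
Unlabeled words are dropped and the remaining class sequence is the
pattern: *"BanHI A rightward transcripts"* yields
`[GeneSymbol][Specifier][RNAKeyword]` with ratio 3/4. Identical sequences
are deduplicated with counts, ordered by count then lexicographically, so
pattern files are reproducible.

Matching a pattern against a labeled sentence allows two edit operations,
with limits chosen to keep matching local and decodable:

* **Insertion** of sentence words inside the span — at most
  `max_insert_run = 2` consecutive tokens between adjacent matched
  concepts, and never outside the first/last match (so spans always start
  and end on matched concepts).
* **Deletion** of pattern concepts — interior concepts only, at most
  `⌊(len−1)/2⌋`, so a majority of the pattern, including both anchors,
  must be present.

All legal alignments are enumerated; per span only the best-scoring
alignment is kept (ties: fewer insertions, then fewer deletions). The
score is `logistic(W · f + b)` over alignment counts (matched / inserted /
deleted, per-concept match indicators), a ±1-token context window (word
and POS identities; the width is our choice, the smallest window that
distinguishes *"... receptors were"* from *"... receptors gene"*), and
morphology flags of span tokens (capitalization, digits, hyphen, Greek
words). Weights are tuned by ridge-penalized logistic regression (glmnet,
`alpha = 0`, fixed `lambda = 1e-3`, no standardization) on candidates
generated by running all patterns over the training corpus; a candidate is
positive iff its span exactly equals a gold span. The decision threshold
defaults to 0.5 and is configurable. Overlapping predictions are resolved
by score, then span length, then leftmost position — a fixed, documented
order so runs are identical.

## The CRF recognizer

Sentences are tokenized (hyphenated words stay whole, other punctuation
splits off), then *sub-tokenized* at letter/digit/other boundaries
(`VLA-4` → `VLA | - | 4`), because gold GPRO spans may cut through tokens.
Mentions are snapped outward to sub-token boundaries during encoding. The
SOBIE scheme uses nine labels — `{B, I, E, S} × {Type 1, Type 2}` plus `O`.
Decoding tolerates ill-formed model output with a fixed repair rule: a
leading `I` (or a type switch mid-run) opens a new mention as if it were
`B`, and an unterminated run closes at its last in-type token.

Per sub-token features: the digit-normalized lowercased word (`IL-2` →
`il-0`), POS and chunk tags, prefixes/suffixes of lengths 2–4, word shape
(`p53` → `a00`) and collapsed shape, orthographic flags, and the SPBA
feature — the SOBIE-style position of the sub-token inside any overlapping
SPBA gene mention, or `O`. Word, POS and SPBA features repeat over a ±2
window. Window width and affix lengths follow common chemical-NER
practice; they are deliberate defaults, not tuned values. The ablation
switch removes only the SPBA group, leaving every other feature
untouched, so feature-set comparisons are clean.

Training minimizes the L2-penalized negative log-likelihood (`l2 = 0.1`
on all parameters, including transitions and start/end weights) with
L-BFGS from a zero start, for at most 150 iterations; the gradient comes
from forward–backward in compiled code, prediction from Viterbi. With a
fixed input order the whole procedure is deterministic — training twice
yields byte-identical parameters. POS/chunk tagging is a pluggable
function; the bundled fallback is a deterministic regex tagger, so no
external model is required.

## Post-processing

Four steps, applied in this order, each independently switchable (all off
= identity):

1. **Identifier mapping** (optional — it lowered recall in the original
   task setting, so it is switchable; skipped when no table is supplied):
   surfaces are normalized (lowercase, strip non-alphanumerics, strip one
   trailing `s` — left alone after `ss` so the map is idempotent), looked
   up, homolog ids collapsed to human ids; exactly one id → Type 1,
   anything else → Type 2.
2. **Tag consistency**: untagged token-boundary occurrences of recognized
   surfaces — or of their abbreviation/full-form partners found by the
   parenthesis + letter-subsequence heuristic — are added with the same
   type, leftmost-longest, never overlapping existing mentions.
3. **Annotation-standard span rules**: *"full (ABBR) receptor"* merges
   into one mention (the plural *receptors* is accepted by default, as an
   explicit extension flag); a two-token mention ending in *protein* whose
   first token has ≥ 3 characters drops the keyword; a single-word mention
   shorter than 3 characters absorbs a following *protein*. The "length of
   the abbreviation" in the first short-name rule is read as the length of
   the mention's first token.
4. **Blacklist filtering** removes predictions whose normalized surface is
   a known chemical/drug term.

## Evaluation

Micro-averaged precision/recall/F1 as percentages, in four
configurations: strict (exact span) or relaxed (≥ 1 character of overlap,
the loosest defensible reading of "partial match"), crossed with Type 1
only or Types 1 + 2 combined. Combined scoring ignores the predicted type
label by default; `respect_type = TRUE` gives the stricter alternative
since the reference scorer's behavior is not documented. Matching is
one-to-one and greedy, gold scanned left to right, each taking the
leftmost unused matching prediction; with non-overlapping mention sets on
each side this agrees with optimal bipartite matching (verified in the
tests against an exhaustive matcher). Zero denominators score 0.

## The synthetic fixture generator

Real GPRO corpora are not redistributable, so the package generates its
own study conditions: patent-abstract-shaped documents (one-sentence
title, 2–3 sentence abstract) over pronounceable nonsense vocabulary, with
mentions planted from the concept templates `[GeneSymbol]`,
`[GeneSymbol][ProteinKeyword]`, `[Taxonomy][GeneSymbol][ProteinKeyword]`
and `[ProteinKeyword][GeneSymbol]`. Defaults, chosen once as the
benchmark conditions: 200 documents, 60 gene symbols, 50% of mention
surfaces carrying exactly one database id (`type1_fraction = 0.5`), a 15%
chance of an unlabeled word inserted inside a mention (exercising SPBA's
insertion tolerance), a 10% distractor-term rate, and 20% of gene symbols
held out of the training half while remaining in the CKB. Gene symbols
deliberately span five shape styles — all-caps, caps+digit, hyphenated,
capitalized word-like and plain lowercase word-like — so that surface
shape alone cannot identify them and dictionary knowledge genuinely
matters; this is what makes the held-out symbols a meaningful probe of the
SPBA feature group. Everything derives from one seed; the same spec
produces byte-identical files.

What the generator does *not* emulate: real nomenclature ambiguity
(symbols that are English words in non-gene senses), type conventions
driven by database content rather than by surface assignment, sentence
syntax beyond bag-of-filler, and annotation noise. Passing the synthetic
benchmark therefore shows the machinery is correct and that the SPBA
features carry dictionary information the CRF lacks — it does not predict
absolute scores on real patent corpora, where all four components face far
more ambiguity.

## Problem sizes and numerical choices

The test suite runs the benchmark at 200 documents with a 50/50
train/test split (seed 7), weight-recovery checks on 2000 simulated
candidates, exhaustive alignment checks for patterns up to 4 concepts over
sentences up to 8 tokens, and 200–500 randomized property cases per
invariant — sizes picked so the whole suite stays interactive while every
code path is exercised. L-BFGS convergence uses `factr = 1e7`; glmnet runs
with `thresh = 1e-10`. Degenerate inputs are contract errors where the
operation is meaningless (single-class training data, unsorted label
projections, overlapping mentions fed to the encoder or scorer) and
benign where a sensible identity exists (empty text, empty mention sets,
empty blacklists).

## Known limitations

* The sub-tokenization and sentence-splitting rules are simple stand-ins
  for tagger-grade components; the tagger interface accepts a better one.
* SPBA patterns cannot represent optional structure except through
  deletions, and insertions are capped at two consecutive tokens; long
  coordinated mentions will not match.
* The consistency step propagates exact surfaces only (plus detected
  abbreviations); it does not do fuzzy matching.
* On this synthetic corpus both CRF configurations operate near ceiling on
  symbols seen in training; the dictionary effect is visible on the
  held-out-symbol subset, which is the comparison the acceptance script
  reports.
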