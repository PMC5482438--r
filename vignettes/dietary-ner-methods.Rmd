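---
title: "Two-phase rule-based entity extraction for dietary recommendations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two-phase rule-based entity extraction for dietary recommendations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dietner)
```

## The problem

Evidence-based dietary advice — dietary reference values (DRVs) and
food-based dietary guidelines — mostly lives in free text: "People of any
age who are African Americans should further reduce sodium intake to 300 mg
per day." No annotated corpus exists for this domain, so supervised NER is
not an option. dietner therefore implements a deterministic, rule-based
pipeline that combines shallow parsing, gazetteer lookups, a small amount of
Boolean algebra and matrix arithmetic, and a constituency-tree heuristic to
pull out five kinds of entities:

* **Food**, **Nutrient**, **Quantity/Unit** — the dietary content;
* **Action** — the predicate verb chunk ("should further reduce");
* **Group** — the unlabeled noun chunks that perform the action
  ("People of any age").

Every extracted entity also carries a **Subject/Predicate/Object** label
with a segment subscript (`S1`, `P1`, `O2`, ...) locating it relative to
the Action within its sentence segment.

## Pre-processing

Documents are split into sentences, each sentence is tokenized, POS-tagged
(Penn Treebank tags) and chunked into B-I-O phrases (CoNLL-2000 types:
NP, VP, PP, ADVP, ...). The annotator is a *backend contract*, not a fixed
tagger: any component producing aligned token/POS/chunk columns plugs in.
Two backends ship with the package:

* a built-in rule-based tagger/chunker (closed-class word lists, suffix
  heuristics, a tag-pattern chunker) — dependency-free and deterministic,
  adequate for plain declarative recommendation prose;
* a fixture backend that replays stored annotations from TSV files, which
  is what all reference tests use, so their outcomes are independent of
  any tagger's quality.

A sentence is then split into **segments** at every ADVP, CONJP or SBAR
chunk and at every pair of successive outside-chunk (O, O) tokens. Design
choices here, made once:

* the boundary sits before the first O of a pair, and inside longer O runs
  between every two O tokens, so no emitted segment can retain an (O, O)
  pair (this makes splitting idempotent);
* the trigger chunk's tokens are removed; O-tagged punctuation adjacent to
  a boundary is dropped; other O tokens stay with the following segment;
* double quotation marks and brackets are removed everywhere;
* segments are numbered 1..s in order of appearance, and only emitted
  segments consume an index (a removed trigger-only fragment does not).

Tokenization splits contractions (`'re` is its own token) but keeps
slash-joined units (`mg/day`) and hyphenated compounds (`omega-3`) whole,
because unit mentions frequently take those shapes.

## Phase one: detecting entity mentions

For a segment with $n$ tokens, $m$ chunks (every tag starting `B-`, plus
each single O token) and $k$ entity types (default $k = 3$):

* $X_{\mathrm{Chunks}}$ is the $n \times m$ binary matrix assigning each
  token to its chunk (each row sums to 1);
* $X_{\mathrm{Dictionaries}}$ is the $n \times k$ binary matrix of
  gazetteer hits per token;
* $X_{\mathrm{Entities}} = X_{\mathrm{Chunks}}^{T} \cdot
  X_{\mathrm{Dictionaries}}$ counts, per chunk and entity type, the
  dictionary evidence. A chunk with any entry $\ge 1$ is an entity
  mention.

A chunk with evidence for more than one type is resolved to a single tag:
the type of its *last* dictionary-hit token. When one token belongs to two
dictionaries at once (the magnesium symbol `Mg` is both a nutrient term and,
through its lemma, the milligram unit symbol), the tie goes to the earliest
type in the fixed order Food, Nutrient, Quantity/Unit — which keeps "The
RDAs for Mg" a Nutrient mention.

### Gazetteers

The three bundled lexicons stand behind a pluggable gazetteer interface
that combines any number of sources by an **any-vote union** (one source
accepting a token suffices; adding a source can never remove a member).
Matching rules, each of which is load-bearing for the reference examples:

* lower-case terms match case-insensitively; terms containing an
  upper-case letter (`Mg`, `ALA`) match case-sensitively, so the element
  symbol never collides with the lower-case unit `mg`;
* only the Quantity/Unit gazetteer matches on the **lemma** (a small
  rule-based plural stripper), so `teaspoons` finds `teaspoon`; Food and
  Nutrient terms match on the surface form — deliberately, which is why
  the plural `omega-3s` is missed while `omega-3` is found;
* a slash-compound token matches a unit through its pre-slash prefix
  (`mg/day` matches `mg`);
* multi-word terms (`table salt`, `alpha-linolenic acid`) match contiguous
  token runs, recording the hit on each covered token;
* the unit list is in the style of a units-of-measurement ontology (names
  plus symbols) extended with kitchen units, but deliberately excludes
  bare time words (`day`, `year`): in this domain "per day" is a rate
  qualifier and "50 years" an age, not quantity mentions.

### Post-hoc chunkings

Potential mentions often span several phrases ("the recommended intake for
total fiber", not just "fiber"). Three merge passes repair this:

1. **(NP, PP, NP) trigrams** merge into one noun chunk, *guarded* by a
   Boolean function: the merge is forbidden exactly when the outer chunks
   carry labels of two different entity types (fusing "sodium intake" with
   "300 mg" would lose a mention). With $k$ types the guard is the
   conjunction of $V_{k,2} = k!/(k-2)!$ pairwise functions
   $\neg(A \wedge B)$ — 6 functions for $k = 3$. After a merge the scan
   resumes with the merged chunk as the left element, so merges chain:
   that is what builds "The recommended intake for total fiber for
   adults" out of five chunks. Trigram candidates are counted on the
   incoming chunk sequence, before merges rewrite it.
2. **(NP, VP, NP) trigrams** merge when the first noun chunk contains a
   wh-pronoun (WP, WP$, WDT), fusing relative clauses such as "who are
   African Americans". This pass does *not* chain: a fused relative
   clause must not absorb the main verb that follows it.
3. **(NP, NP) bigrams** merge when exactly one of the two chunks is
   labeled, or both carry the same label; two different labels — or no
   labels at all — block the merge.

Labels are recomputed from the dictionary matrix after every merge, so
pass 3 sees post-merge labels. After all passes, $X_{\mathrm{Chunks}}$ and
$X_{\mathrm{Entities}}$ are **recalculated**; the initial matrix keeps O
rows (sentence punctuation appears as an all-zero row), the recalculated
one keeps phrase chunks only. For the sodium sentence this yields the
6-row by 3-column matrix whose only nonzero cells are ("sodium intake",
Nutrient) and ("300 mg per day", Quantity/Unit).

A known edge of the literal bigram rule: applied after the chained first
pass on the fiber sentence, it can fuse the labeled chunk "…for adults"
with the following "50 years", where treating "50 years" as a separate
Group chunk would also be defensible. The literal rule is implemented;
the fused variant changes no downstream label.

## Phase two: selecting and labeling entities

The segment is viewed as a chain graph over its phrase chunks (each chunk
linked to its neighbors; distance = index difference). The **Action** is
found in a constituency tree: among verb leaves (VB, VBD, VBG, VBN, VBP,
VBZ, MD) inside VP subtrees, pick the one minimizing first the depth of
its shallowest enclosing VP, then its own depth, ties leftmost — the verb
"closest to the root, in the verbal phrase closest to the root". The chunk
containing that leaf is the Action. Two parser backends exist: a reader
for Penn-style bracketed trees (fixtures), and a *shallow* tree built from
the merged chunk sequence (root S over chunk nodes over POS preterminals).
The shallow tree works because phase one already fused relative clauses
into noun chunks, hiding their inner verbs from the VP search; on the
sodium sentence both backends select "should further reduce". When a
parser fails or no VP exists, the segment has no Action.

**Group**: from the Action, walk back toward the segment start collecting
consecutive noun chunks that are *not* entity mentions; O chunks between
them are skipped (punctuation or stray coordinators such as "and" may
separate the performers); any other phrase, or a labeled mention, stops
the walk. Labeled mentions are never reported as Group — they already
appear under their own type.

**Mention selection** has two scenarios. With no Action, every mention is
extracted. With an Action, for each type the mention closest to the
Action is extracted, then the other mentions of the same type on the same
side, and mentions on the far side only if that side contains no verb
chunk other than the Action ("1 teaspoon" survives across "contains"
because the subject side holds no further verb).

**S/P/O**: the Action is `P`; entities before it are `S`; after it, `O`;
with no Action everything is `S`. The subscript is the segment index. A
segment whose recalculated entity matrix is all zero emits nothing at all
— no Action, no Group ("Your hat looks very nice." produces an empty
result).

## Numerical and degenerate-input choices

* All matrices are dense base-R integer matrices; segments are short
  (tens of tokens), so sparse representations would be noise.
* A dangling `I-` tag (no matching `B-`) is a validation error, caught at
  construction of every annotated sentence.
* Empty documents, empty segments and empty gazetteers flow through and
  produce empty results rather than errors.
* Everything is deterministic: repeated runs on the same inputs and
  backends are byte-identical. There is no randomness anywhere in the
  pipeline.

## What the synthetic test segments do and do not show

Property tests draw random B-I-O segments over a small vocabulary that
includes gazetteer terms, with random phrase types and lengths and, where
relevant, injected ADVP triggers and O runs. They exercise the invariants
— token conservation across splitting and merging, chunk-count
monotonicity, row sums of the chunk matrix, equality of the matrix product
with a brute-force count, guard symmetry, S/P/O consistency with chunk
position. They do not emulate real syntax: random POS tags do not
correlate with phrase types, so passing them says nothing about the
linguistic quality of the built-in tagger on real prose. That quality is
bounded separately by the two fully annotated reference sentences, which
run through fixture annotations.

Problem sizes used by the default test run: 100 random matrix instances,
200 random segments for the conservation/monotonicity suite, 60 for the
S/P/O suite — a few seconds on one CPU.

## Known limitations

* The bundled lexicons are small curated lists sufficient for the domain's
  common vocabulary; a production deployment would plug richer gazetteers
  or live annotator adapters into the same interface.
* The built-in tagger and chunker are heuristics; garden-path sentences,
  questions and coordination-heavy NPs will be mis-chunked. Use fixture
  annotations or a stronger backend where exactness matters.
* No entity normalization to ontology identifiers, no fuzzy matching, no
  relation pairing (e.g. linking "1 teaspoon" to "table salt") — the
  output contract is the labeled entity tuples.
* English only; no coreference.
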