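# dietner

Rule-based named-entity recognition for dietary recommendation text.

Dietary reference values and food-based guidelines are mostly published as
free text ("People of any age who are African Americans should further
reduce sodium intake to 300 mg per day."), and no annotated corpus exists
that would support supervised NER in this domain. dietner extracts the
dietary content of such sentences — **Food**, **Nutrient** and
**Quantity/Unit** entity mentions, plus the **Action** (predicate verb
chunk) and the **Group** (who performs the action) — and labels every
entity as **S**ubject, **P**redicate or **O**bject with a sentence-segment
subscript. It is aimed at nutrition informatics: building structured
knowledge bases of recommendations from authority web sites and abstracts.

## Method

The pipeline is deterministic and has two phases, run per sentence segment
(sentences are split at ADVP/CONJP/SBAR chunks and at successive
outside-chunk token pairs):

1. **Mention detection.** With `n` tokens, `m` shallow-parse chunks and
   `k` entity types, two binary matrices are built — `X_Chunks` (`n x m`,
   token-to-chunk membership) and `X_Dictionaries` (`n x k`, gazetteer
   hits) — and multiplied:

   `X_Entities = t(X_Chunks) %*% X_Dictionaries`

   A chunk with any entry ≥ 1 is an entity mention (multi-type chunks
   resolve to the type of their last dictionary-hit token). Three post-hoc
   chunking passes then merge adjacent chunks into larger entity-bearing
   noun phrases: guarded `(NP, PP, NP)` trigrams — the Boolean guard, a
   conjunction of `V(k,2) = k!/(k-2)!` pairwise functions `!(A & B)`,
   forbids fusing mentions of two different types — wh-pronoun
   `(NP, VP, NP)` trigrams, and label-compatible `(NP, NP)` bigrams.
   `X_Entities` is finally recalculated over the merged phrase chunks.
2. **Selection and labeling.** The Action is the verb leaf closest to the
   root of a constituency tree (shallowest enclosing VP first, then leaf
   depth, ties leftmost); the Group is the run of unlabeled noun chunks
   walking back from the Action; mentions are selected by chain-graph
   distance to the Action (far-side mentions only when that side has no
   other verb chunk); entities before/at/after the Action get S/P/O.

Tokenization, tagging and chunking sit behind a pluggable backend
(a built-in rule tagger/chunker and a fixture-file replay backend are
bundled), as does parsing (bracketed-tree reader, shallow chunk tree).
Gazetteers are any-vote term-list unions; units are matched on lemmas,
`Mg`-style symbols case-sensitively. See the vignette in `vignettes/` for
the full account of the rules and their rationale.

## Worked example

```r
library(dietner)
ents <- extract_document(
  "People of any age who are African Americans should further reduce
   sodium intake to 300 mg per day. 1 teaspoon of table salt contains
   2300 mg of sodium.")
ents[, c("text", "entity_type", "spo", "label", "sentence_index")]
```

```
                        text  entity_type spo label sentence_index
1          People of any age        Group   S    S1              1
2  who are African Americans        Group   S    S1              1
3      should further reduce       Action   P    P1              1
4              sodium intake     Nutrient   O    O1              1
5             300 mg per day QuantityUnit   O    O1              1
6                 1 teaspoon QuantityUnit   S    S1              2
7                 table salt         Food   S    S1              2
8                   contains       Action   P    P1              2
9                    2300 mg QuantityUnit   O    O1              2
10                    sodium     Nutrient   O    O1              2
```

Reading the labels: in sentence 1 the Group "People of any age / who are
African Americans" (subject) should-further-reduce (predicate) the
Nutrient "sodium intake" to the Quantity "300 mg per day" (objects). In
sentence 2 the subject-side quantity "1 teaspoon" belongs with the Food
"table salt", and the object-side "2300 mg" with the Nutrient "sodium" —
the S/O labels are what make that pairing readable.

Command line:

```sh
Rscript inst/scripts/dietner --input inst/extdata/example_recommendations.txt \
    --format json --output out.jsonl
```

Formats: JSON lines, TSV, and BRAT standoff (`T` spans + `A` S/P/O
attributes, offsets 0-based end-exclusive into the input document).

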