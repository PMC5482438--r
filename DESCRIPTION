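Package: dietner
Title: Rule-Based Named-Entity Recognition for Dietary Recommendation Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extracts Food, Nutrient and Quantity/Unit entity mentions,
    together with Action and Group entities and Subject/Predicate/Object
    labels, from free-text dietary recommendations. Implements a two-phase
    rule-based pipeline: phase one detects entity mentions by combining
    shallow-parse (B-I-O) chunks with gazetteer lookups through binary
    membership matrices and merges adjacent chunks with three guarded
    post-hoc chunking passes; phase two selects the predicate verb chunk
    from a constituency tree, harvests the noun chunks that perform the
    action, and labels every extracted entity as subject, predicate or
    object. Annotation and parsing backends are pluggable; fixture files
    with pre-computed annotations make every step reproducible offline.
    Writers for JSON-lines, TSV and BRAT standoff output and a command-line
    driver are included.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stringr,
    tibble
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
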