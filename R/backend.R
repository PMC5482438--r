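#' Annotation backends
#'
#' An annotation backend turns a sentence string into an aligned
#' token/POS/chunk annotation (an `annotated_sentence`). Any backend honouring
#' Penn-Treebank POS tags and CoNLL-2000 chunk phrase types can be plugged in;
#' two are bundled:
#'
#' * `builtin_annotation_backend()` — a self-contained rule-based tokenizer,
#'   POS tagger and chunker (closed-class word lists plus suffix heuristics,
#'   then a tag-pattern chunker). Deterministic and dependency-free; adequate
#'   for plain declarative recommendation sentences, not a general parser.
#' * `fixture_annotation_backend()` — replays pre-computed annotations (e.g.
#'   read with [read_fixture_annotation()]), matched against the input by
#'   whitespace-normalized text or token sequence. If a sentence has no
#'   fixture, the `fallback` backend is consulted; with `fallback = NULL` an
#'   error of class `dietner_backend_error` is raised, which distinguishes a
#'   missing annotation from malformed input.
#'
#' @param annotations list of `annotated_sentence` objects (or a single one).
#' @param fallback another backend consulted on a fixture miss, or `NULL`.
#' @return an object of class `dietner_backend`: a list with an `annotate`
#'   function and a `name`.
#' @seealso [annotate_tokens()]
#' @examples
#' be <- builtin_annotation_backend()
#' ann <- annotate_tokens("Babies need protein.", be)
#' ann$token
#' @export
builtin_annotation_backend <- function() {
  structure(
    list(name = "builtin", annotate = function(sentence) builtin_annotate(sentence)),
    class = "dietner_backend"
  )
}

#' @rdname builtin_annotation_backend
#' @export
fixture_annotation_backend <- function(annotations, fallback = NULL) {
  if (inherits(annotations, "annotated_sentence")) annotations <- list(annotations)
  stopifnot(all(vapply(annotations, inherits, logical(1), "annotated_sentence")))
  keys <- vapply(annotations, function(a) normalize_sentence_key(attr(a, "text")), character(1))
  tok_keys <- vapply(annotations, function(a) normalize_sentence_key(paste(a$token, collapse = " ")),
                     character(1))
  structure(
    list(
      name = "fixture",
      annotate = function(sentence) {
        key <- normalize_sentence_key(sentence)
        hit <- match(key, keys)
        if (is.na(hit)) hit <- match(key, tok_keys)
        if (!is.na(hit)) {
          ann <- annotations[[hit]]
          attr(ann, "text") <- sentence
          return(ann)
        }
        if (!is.null(fallback)) return(fallback$annotate(sentence))
        stop(backend_error(sprintf("no fixture annotation for sentence: %s", sentence)))
      }
    ),
    class = "dietner_backend"
  )
}

backend_error <- function(msg) {
  structure(class = c("dietner_backend_error", "error", "condition"),
            list(message = msg, call = NULL))
}

# Key used to match fixture annotations to raw sentences: lower-cased, all
# non-alphanumerics stripped, so tokenization and quote style do not matter.
normalize_sentence_key <- function(x) {
  x <- tolower(x)
  gsub("[^a-z0-9]+", "", x)
}

## ---- tokenizer -------------------------------------------------------------

# Penn-style word tokenizer. Contractions split off ('re, n't, 's, ...);
# slash- and hyphen-joined alphanumerics stay one token (mg/day, omega-3,
# 4-6); other punctuation is its own token. Returns a data.frame with the
# token and its character span (1-based, inclusive) in the input.
TOKEN_PATTERN <- paste(
  "[A-Za-z]+(?=n't)",               # do | n't
  "n't",
  "'(?:re|ve|ll|s|d|m|t)\\b",
  "[0-9]+(?:[.,][0-9]+)*(?:[-/][A-Za-z0-9.]+)*%?", # 2,300  4-6  2.5  76%
  "[A-Za-z][A-Za-z0-9]*(?:[-/][A-Za-z0-9]+)*",     # mg/day low-fat omega-3
  "\\S",                            # any remaining single non-space char
  sep = "|"
)

tokenize_words <- function(sentence) {
  sentence <- normalize_quotes(sentence)
  m <- gregexpr(TOKEN_PATTERN, sentence, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0)))
  }
  starts <- as.integer(m)
  ends <- starts + attr(m, "match.length") - 1L
  data.frame(token = substring(sentence, starts, ends), start = starts, end = ends)
}

normalize_quotes <- function(x) {
  x <- gsub("’|‘", "'", x)
  gsub("“|”", "\"", x)
}

#' Lemmatize a token
#'
#' Minimal rule-based lemmatizer: lower-cases and strips regular plural
#' suffixes (`teaspoons` to `teaspoon`, `berries` to `berry`, `dishes` to
#' `dish`). Used for Quantity/Unit dictionary lookups, where singular and
#' plural unit names must collapse.
#'
#' @param token character vector of surface tokens.
#' @return character vector of lemmas (lower-cased).
#' @examples
#' lemma(c("Teaspoons", "grams", "dishes", "berries", "glass"))
#' @export
lemma <- function(token) {
  x <- tolower(token)
  out <- x
  ies <- grepl("[a-z]ies$", x)
  out[ies] <- sub("ies$", "y", x[ies])
  es <- !ies & grepl("(ch|sh|ss|x|z)es$", x)
  out[es] <- sub("es$", "", x[es])
  s <- !ies & !es & grepl("[a-z]s$", x) & !grepl("(ss|us|is)$", x)
  out[s] <- sub("s$", "", x[s])
  out
}

## ---- POS tagger ------------------------------------------------------------

POS_LEXICON <- local({
  lex <- c(
    the = "DT", a = "DT", an = "DT", this = "DT", these = "DT", those = "DT",
    any = "DT", some = "DT", all = "DT", each = "DT", every = "DT", no = "DT",
    both = "DT", other = "JJ", another = "DT",
    of = "IN", `in` = "IN", on = "IN", at = "IN", by = "IN", `for` = "IN",
    with = "IN", from = "IN", per = "IN", about = "IN", over = "IN",
    under = "IN", after = "IN", before = "IN", between = "IN", during = "IN",
    without = "IN", than = "IN", into = "IN", through = "IN", `if` = "IN",
    because = "IN", `while` = "IN", due = "IN", instead = "IN",
    to = "TO",
    and = "CC", or = "CC", but = "CC", nor = "CC", plus = "CC",
    should = "MD", could = "MD", would = "MD", can = "MD", may = "MD",
    might = "MD", must = "MD", will = "MD", shall = "MD",
    i = "PRP", you = "PRP", he = "PRP", she = "PRP", it = "PRP", we = "PRP",
    they = "PRP", them = "PRP", him = "PRP", us = "PRP", me = "PRP",
    my = "PRP$", your = "PRP$", his = "PRP$", its = "PRP$", our = "PRP$",
    their = "PRP$",
    who = "WP", whom = "WP", what = "WP", which = "WDT", whose = "WP$",
    `when` = "WRB", according = "VBG",
    there = "EX",
    is = "VBZ", are = "VBP", am = "VBP", was = "VBD", were = "VBD",
    be = "VB", been = "VBN", being = "VBG",
    has = "VBZ", have = "VBP", had = "VBD",
    does = "VBZ", `do` = "VBP", did = "VBD",
    not = "RB", very = "RB", also = "RB", however = "RB",
    respectively = "RB", only = "RB", just = "RB", too = "RB",
    further = "RBR", more = "JJR", less = "JJR", most = "JJS",
    younger = "JJR", older = "JJR", good = "JJ", many = "JJ", much = "JJ",
    new = "JJ", high = "JJ", low = "JJ", whole = "JJ", extra = "JJ",
    sufficient = "JJ", excellent = "JJ", first = "JJ", total = "JJ",
    daily = "JJ", recommended = "VBN", `'re` = "VBP", `'m` = "VBP",
    `'s` = "POS", `'ve` = "VBP", `'ll` = "MD", `'d` = "MD", `n't` = "RB"
  )
  # Common open-class verbs of recommendation text, base/inflected.
  vb <- c("eat", "need", "get", "look", "choose", "include", "contain",
          "provide", "reduce", "increase", "decrease", "add", "limit",
          "avoid", "drink", "consume", "try", "make", "set", "keep",
          "order", "store", "serve", "cook", "help")
  lex[vb] <- "VBP"
  lex[paste0(sub("e$", "", vb), "es")] <- "VBZ"
  lex[c("needs", "gets", "looks", "contains", "provides", "includes",
        "reduces", "helps", "makes", "keeps")] <- "VBZ"
  lex[c("trying", "eating", "ordering", "looking", "getting", "cooking",
        "serving")] <- "VBG"
  lex[c("enriched", "steamed", "roasted", "ingested", "decreased",
        "increased", "fortified", "added")] <- "VBN"
  lex
})

tag_pos <- function(tokens) {
  n <- length(tokens)
  tags <- character(n)
  low <- tolower(tokens)
  for (i in seq_len(n)) {
    tok <- tokens[i]
    tg <- unname(POS_LEXICON[low[i]])
    if (!is.na(tg) && length(tg)) {
      tags[i] <- tg
    } else if (grepl("^[0-9]", tok)) {
      tags[i] <- "CD"
    } else if (tok %in% c(".", "!", "?")) {
      tags[i] <- "."
    } else if (tok == ",") {
      tags[i] <- ","
    } else if (tok %in% c(":", ";", "-", "--")) {
      tags[i] <- ":"
    } else if (is_punct_token(tok)) {
      tags[i] <- "SYM"
    } else if (grepl("ing$", low[i]) && nchar(tok) > 4) {
      tags[i] <- "VBG"
    } else if (grepl("ly$", low[i]) && nchar(tok) > 3) {
      tags[i] <- "RB"
    } else if (grepl("ed$", low[i]) && nchar(tok) > 3) {
      tags[i] <- "VBN"
    } else if (i > 1 && grepl("^[A-Z]", tok)) {
      tags[i] <- if (grepl("s$", tok)) "NNPS" else "NNP"
    } else if (grepl("s$", low[i]) && !grepl("(ss|us|is)$", low[i])) {
      tags[i] <- "NNS"
    } else {
      tags[i] <- "NN"
    }
  }
  # Base verbs after "to" or a modal.
  for (i in seq_len(n)) {
    if (i > 1 && tags[i] %in% c("VBP", "VBZ") && tags[i - 1] %in% c("TO", "MD")) {
      tags[i] <- "VB"
    }
  }
  tags
}

## ---- chunker ---------------------------------------------------------------

# Tag-pattern chunker in the CoNLL-2000 style. Nominal tags glue into NPs,
# verbal tags (with medial adverbs and infinitival "to") into VPs,
# prepositions open PPs, free adverbs open ADVPs, coordinators and
# punctuation stay outside.
NOMINAL_TAGS <- c("DT", "PDT", "PRP$", "JJ", "JJR", "JJS", "CD",
                  "NN", "NNS", "NNP", "NNPS", "PRP", "WP", "WDT", "EX", "POS")
NP_STARTERS <- c("DT", "PRP", "WP", "WDT", "EX") # open a fresh NP even after one

chunk_tags_rule <- function(tokens, pos) {
  n <- length(pos)
  out <- character(n)
  prev <- "" # chunk type the previous token ended in ("" = none/O)
  for (i in seq_len(n)) {
    tg <- pos[i]
    nxt <- if (i < n) pos[i + 1] else ""
    if (tg %in% c(".", ",", ":", "SYM", "''", "``")) {
      out[i] <- "O"; prev <- ""
    } else if (tg == "CC") {
      out[i] <- "O"; prev <- ""
    } else if (tg %in% VERB_TAGS && !(tg == "VBN" && prev == "NP" && nxt %in% NOMINAL_TAGS)) {
      out[i] <- if (prev == "VP") "I-VP" else "B-VP"; prev <- "VP"
    } else if (tg == "TO" && nxt %in% c("VB", "VBP")) {
      out[i] <- if (prev == "VP") "I-VP" else "B-VP"; prev <- "VP"
    } else if (tg %in% c("RB", "RBR", "RBS")) {
      if (prev == "VP" && nxt %in% VERB_TAGS) {
        out[i] <- "I-VP" # medial adverb: should *further* reduce
      } else {
        out[i] <- "B-ADVP"; prev <- "ADVP"
      }
    } else if (tg %in% c("IN", "TO")) {
      out[i] <- if (prev == "PP") "I-PP" else "B-PP"; prev <- "PP"
    } else if (tg %in% NOMINAL_TAGS || tg == "VBN") {
      if (prev == "NP" && !(tg %in% NP_STARTERS)) {
        out[i] <- "I-NP"
      } else {
        out[i] <- "B-NP"
      }
      prev <- "NP"
    } else {
      out[i] <- "O"; prev <- ""
    }
  }
  out
}

builtin_annotate <- function(sentence) {
  td <- tokenize_words(sentence)
  pos <- tag_pos(td$token)
  chunk <- chunk_tags_rule(td$token, pos)
  new_annotated_sentence(td$token, pos, chunk, text = sentence,
                         start = td$start, end = td$end)
}
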