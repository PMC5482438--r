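#' Gazetteers: per-entity-type token membership
#'
#' A gazetteer answers, deterministically, whether a token belongs to one
#' entity type's vocabulary. It is the pluggable stand-in for the external
#' annotator ensembles a live deployment might use: any number of sources
#' (term sets) can back one gazetteer, combined by an any-vote union — a
#' token is a member if at least one source accepts it, so adding a source
#' can only add members.
#'
#' Matching modes:
#' * `"surface"` — the token's surface form is looked up; all-lower-case
#'   terms match case-insensitively, terms containing an upper-case letter
#'   (element symbols such as `Mg`, acronyms such as `ALA`) match
#'   case-sensitively so they cannot collide with unit symbols.
#' * `"lemma"` — the token's [lemma()] is looked up (used for Quantity/Unit,
#'   collapsing singular/plural unit names); a slash-compound token also
#'   matches through its pre-slash prefix (`mg/day` matches `mg`).
#'
#' Multi-word terms (e.g. `table salt`) match when all their words appear as
#' contiguous tokens; the hit is recorded on each covered token.
#'
#' @param entity_type one of the gazetteer's entity-type names.
#' @param terms character vector of terms (single- or multi-word).
#' @param match_mode `"surface"` or `"lemma"`.
#' @return an object of class `gazetteer`.
#' @seealso [load_lexicon()], [token_memberships()]
#' @export
gazetteer <- function(entity_type, terms, match_mode = c("surface", "lemma")) {
  match_mode <- match.arg(match_mode)
  terms <- unique(trimws(terms[nzchar(trimws(terms))]))
  cased <- grepl("[A-Z]", terms)
  structure(
    list(
      entity_type = entity_type,
      match_mode = match_mode,
      # exact (case-sensitive) and folded (case-insensitive) single-word sets
      exact = terms[cased & !grepl("\\s", terms)],
      folded = tolower(terms[!cased & !grepl("\\s", terms)]),
      multiword = lapply(terms[grepl("\\s", terms)],
                         function(t) strsplit(t, "\\s+")[[1]]),
      n_terms = length(terms)
    ),
    class = "gazetteer"
  )
}

#' @export
print.gazetteer <- function(x, ...) {
  cat(sprintf("<gazetteer> %s: %d terms (%s matching)\n",
              x$entity_type, x$n_terms, x$match_mode))
  invisible(x)
}

#' Load a gazetteer from a lexicon file
#'
#' Lexicon files are UTF-8 TSV with two columns, `term<TAB>entity_type`;
#' `#` lines are comments. Duplicate `(term, type)` pairs are dropped with a
#' message. The Quantity/Unit gazetteer uses lemma matching; others match on
#' the surface form.
#'
#' @param path lexicon file path.
#' @param entity_type entity-type name the file provides terms for; entries
#'   carrying a different type are a configuration error.
#' @return a [gazetteer()].
#' @examples
#' p <- system.file("extdata/lexicon/unit.tsv", package = "dietner")
#' g <- load_lexicon(p, "QuantityUnit")
#' @export
load_lexicon <- function(path, entity_type) {
  if (!file.exists(path)) stop(sprintf("lexicon file not found: %s", path))
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  if (length(lines) == 0) {
    return(gazetteer(entity_type, character(0),
                     match_mode = if (entity_type == "QuantityUnit") "lemma" else "surface"))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) != 2)) {
    stop(sprintf("lexicon file %s: every entry needs term<TAB>entity_type", path))
  }
  term <- vapply(fields, `[[`, character(1), 1)
  type <- vapply(fields, `[[`, character(1), 2)
  if (any(type != entity_type)) {
    stop(sprintf("lexicon file %s: unknown/unexpected entity type(s): %s",
                 path, paste(unique(setdiff(type, entity_type)), collapse = ", ")))
  }
  dup <- duplicated(tolower(term))
  if (any(dup)) {
    message(sprintf("load_lexicon: dropped %d duplicate entr%s from %s",
                    sum(dup), if (sum(dup) == 1) "y" else "ies", basename(path)))
    term <- term[!dup]
  }
  gazetteer(entity_type, term,
            match_mode = if (entity_type == "QuantityUnit") "lemma" else "surface")
}

#' Bundled default gazetteers
#'
#' Loads the three lexicons shipped with the package (Food, Nutrient,
#' Quantity/Unit), in the fixed entity-type order used for all matrix
#' columns. `lexicon_dir` may point at a directory containing `food.tsv`,
#' `nutrient.tsv` and `unit.tsv` to swap in custom lists.
#'
#' @param lexicon_dir directory with the three lexicon files.
#' @return named list of three [gazetteer()]s.
#' @export
default_gazetteers <- function(lexicon_dir = system.file("extdata", "lexicon",
                                                         package = "dietner")) {
  list(
    Food = load_lexicon(file.path(lexicon_dir, "food.tsv"), "Food"),
    Nutrient = load_lexicon(file.path(lexicon_dir, "nutrient.tsv"), "Nutrient"),
    QuantityUnit = load_lexicon(file.path(lexicon_dir, "unit.tsv"), "QuantityUnit")
  )
}

# Single-token membership against one gazetteer (ignoring multiword terms,
# which need sentence context; see dictionary_membership_matrix).
single_token_member <- function(token, gaz) {
  if (gaz$match_mode == "lemma") {
    lem <- lemma(token)
    if (lem %in% gaz$folded || token %in% gaz$exact) return(TRUE)
    # slash compounds: mg/day matches through the pre-slash prefix
    if (grepl("/", lem, fixed = TRUE)) {
      pre <- sub("/.*$", "", lem)
      if (pre %in% gaz$folded) return(TRUE)
    }
    FALSE
  } else {
    token %in% gaz$exact || tolower(token) %in% gaz$folded
  }
}

#' Token membership vector across gazetteers
#'
#' The per-token dictionary lookup: component `l` is 1 iff any source of
#' gazetteer `l` accepts the token. Quantity/Unit gazetteers consult the
#' token's lemma, the rest the surface form. Multi-word terms are handled at
#' the sentence level by [build_dictionary_matrix()]; this single-token view
#' covers single-word terms only.
#'
#' @param token one surface token.
#' @param gazetteers list of [gazetteer()]s, ordered as the entity types.
#' @return binary integer vector of length `length(gazetteers)`, named by
#'   entity type.
#' @examples
#' gz <- default_gazetteers()
#' token_memberships("sodium", gz)
#' @export
token_memberships <- function(token, gazetteers) {
  stopifnot(length(token) == 1)
  out <- vapply(gazetteers, function(g) as.integer(single_token_member(token, g)),
                integer(1))
  names(out) <- vapply(gazetteers, `[[`, character(1), "entity_type")
  out
}
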