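#' Select the Action chunk from a parse tree
#'
#' The Action entity is the predicate verb chunk. The search runs over the
#' tree's verbal phrases: every verb leaf (VB, VBD, VBG, VBN, VBP, VBZ, MD)
#' located inside a VP subtree is a candidate; the winner minimizes, in
#' order, the depth of its shallowest enclosing VP and then its own depth
#' (edges from the root), ties broken leftmost. The chunk containing the
#' winning leaf is the Action. `NA` when the segment has no verbal phrase.
#'
#' @param tree a `parse_node` whose leaves align with the segment's tokens.
#' @param chunks chunk tibble of the segment (merged chunks of phase one).
#' @return the Action chunk's index into `chunks`, or `NA_integer_`.
#' @export
select_action <- function(tree, chunks) {
  cand <- verb_candidates(tree)
  if (nrow(cand) == 0) return(NA_integer_)
  ord <- order(cand$vp_depth, cand$depth, cand$index)
  leaf <- cand$index[ord[1]]
  hit <- which(chunks$start <= leaf & chunks$end >= leaf)
  if (length(hit) == 0) return(NA_integer_)
  as.integer(hit[1])
}

#' Harvest Group chunks preceding the Action
#'
#' Group entities are the noun chunks that perform the action: starting at
#' the Action and walking back toward the beginning of the segment, the
#' successive noun chunks are collected. Outside-chunk (O) tokens between
#' them — punctuation or stray coordinators — are skipped; the walk stops at
#' any other phrase or at a noun chunk that is already an entity mention
#' (those are reported under their entity type, not as Group).
#'
#' @param chunks chunk tibble.
#' @param action Action chunk index (from [select_action()]).
#' @param resolved per-chunk resolved entity labels (character, `NA` for
#'   non-mentions), aligned with `chunks`.
#' @return integer vector of Group chunk indices, in sentence order.
#' @export
select_group <- function(chunks, action, resolved) {
  if (is.na(action) || action <= 1) return(integer(0))
  out <- integer(0)
  i <- action - 1L
  while (i >= 1) {
    if (chunks$phrase_type[i] == "O") {
      i <- i - 1L
      next
    }
    if (chunks$phrase_type[i] == "NP" && is.na(resolved[i])) {
      out <- c(i, out)
      i <- i - 1L
      next
    }
    break
  }
  out
}

#' Select entity mentions relative to the Action
#'
#' Two scenarios. Without an Action, every entity mention is extracted. With
#' an Action, for each entity type the mention closest to the Action in the
#' chain graph (edge distance = difference of chunk indices) is extracted
#' first; additional mentions of the same type are extracted when they lie
#' on the same side of the Action, or on the other side provided that side
#' contains no verbal phrase besides the Action itself.
#'
#' @param entity an `entity_matrix` over phrase chunks (recalculated).
#' @param chunks the matching phrase-chunk tibble.
#' @param action Action chunk index into `chunks`, or `NA`.
#' @return named list (by entity type) of integer chunk indices.
#' @export
select_entities <- function(entity, chunks, action) {
  resolved <- attr(entity, "resolved")
  types <- colnames(entity)
  out <- stats::setNames(vector("list", length(types)), types)
  has_vp <- chunks$phrase_type == "VP"
  for (tp in types) {
    mentions <- which(!is.na(resolved) & resolved == tp)
    if (length(mentions) == 0) {
      out[[tp]] <- integer(0)
      next
    }
    if (is.na(action)) {
      out[[tp]] <- mentions
      next
    }
    d <- abs(mentions - action)
    closest <- mentions[order(d, mentions)][1]
    side <- sign(closest - action)
    keep <- closest
    for (m in setdiff(mentions, closest)) {
      m_side <- sign(m - action)
      if (m_side == side) {
        keep <- c(keep, m)
      } else {
        far <- if (m_side < 0) seq_len(action - 1L) else
          seq_len(nrow(chunks))[seq_len(nrow(chunks)) > action]
        if (!any(has_vp[far])) keep <- c(keep, m)
      }
    }
    out[[tp]] <- sort(keep)
  }
  out
}

#' Assign Subject/Predicate/Object labels
#'
#' The Action is the Predicate (`P`). Entities in chunks preceding the
#' Action are Subjects (`S`); those following it are Objects (`O`). When a
#' segment has no Action, all extracted entities are labeled `S`. Every
#' label carries the segment index as subscript (`S1`, `P2`, ...).
#'
#' @param selected named list of chunk indices per entity type (from
#'   [select_entities()]).
#' @param group integer vector of Group chunk indices.
#' @param action Action chunk index or `NA`.
#' @param chunks phrase-chunk tibble.
#' @param segment_index,sentence_index 1-based provenance indices.
#' @return a tibble of extracted entities: `text`, `entity_type`, `spo`,
#'   `label`, `sentence_index`, `segment_index`, `chunk_index`,
#'   `token_start`, `token_end`.
#' @export
assign_spo <- function(selected, group, action, chunks,
                       segment_index = 1L, sentence_index = 1L) {
  rows <- list()
  add <- function(idx, type) {
    for (i in idx) {
      spo <- if (is.na(action)) "S"
        else if (i < action) "S"
        else if (i == action) "P"
        else "O"
      rows[[length(rows) + 1L]] <<- list(
        text = chunks$text[i], entity_type = type, spo = spo,
        chunk_index = as.integer(i),
        token_start = chunks$start[i], token_end = chunks$end[i]
      )
    }
  }
  add(group, "Group")
  if (!is.na(action)) add(action, "Action")
  for (tp in names(selected)) add(selected[[tp]], tp)
  if (length(rows) == 0) return(empty_entities())
  out <- tibble::tibble(
    text = vapply(rows, `[[`, character(1), "text"),
    entity_type = vapply(rows, `[[`, character(1), "entity_type"),
    spo = vapply(rows, `[[`, character(1), "spo"),
    label = paste0(vapply(rows, `[[`, character(1), "spo"), segment_index),
    sentence_index = as.integer(sentence_index),
    segment_index = as.integer(segment_index),
    chunk_index = vapply(rows, function(r) r$chunk_index, integer(1)),
    token_start = vapply(rows, function(r) as.integer(r$token_start), integer(1)),
    token_end = vapply(rows, function(r) as.integer(r$token_end), integer(1))
  )
  out[order(out$chunk_index), ]
}

empty_entities <- function() {
  tibble::tibble(
    text = character(0), entity_type = character(0), spo = character(0),
    label = character(0), sentence_index = integer(0),
    segment_index = integer(0), chunk_index = integer(0),
    token_start = integer(0), token_end = integer(0)
  )
}

#' Extract entities from one segment
#'
#' Runs both phases on an annotated segment. A segment whose recalculated
#' entity matrix is all zero contributes no output at all — not even Action
#' or Group — since it carries no dietary information.
#'
#' @param segment an `annotated_sentence` (with optional `sentence_index` /
#'   `segment_index` attributes).
#' @param gazetteers ordered list of [gazetteer()]s.
#' @param parser a `dietner_parser` backend.
#' @return tibble of extracted entities (see [assign_spo()]).
#' @export
extract_segment <- function(segment, gazetteers = default_gazetteers(),
                            parser = shallow_parser_backend()) {
  det <- detect_mentions(segment, gazetteers)
  if (nrow(det$recalc$entity) == 0 || all(det$recalc$entity == 0L)) {
    return(empty_entities())
  }
  chunks <- det$recalc$chunks
  tree <- tryCatch(parser$parse(segment, det$merged_chunks),
                   error = function(e) NULL)
  action <- if (is.null(tree)) NA_integer_ else {
    a <- select_action(tree, det$merged_chunks)
    # map from the full merged chunk list to the phrase-only list
    if (is.na(a)) NA_integer_ else {
      hit <- which(chunks$start == det$merged_chunks$start[a])
      if (length(hit)) hit[1] else NA_integer_
    }
  }
  resolved <- attr(det$recalc$entity, "resolved")
  group <- select_group(chunks, action, resolved)
  selected <- select_entities(det$recalc$entity, chunks, action)
  assign_spo(selected, group, action, chunks,
             segment_index = attr(segment, "segment_index") %||% 1L,
             sentence_index = attr(segment, "sentence_index") %||% 1L)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract entities from a document
#'
#' The full pipeline: sentence segmentation, annotation through the backend,
#' segment splitting, phase one (mention detection and post-hoc chunking)
#' and phase two (Action/Group selection, mention selection, S/P/O
#' labeling), concatenated in document order. A sentence whose processing
#' fails is logged as a warning and skipped; the document never aborts.
#'
#' @param text document text (UTF-8; paragraphs of one or more sentences).
#' @param gazetteers ordered list of [gazetteer()]s.
#' @param backend annotation backend, see [builtin_annotation_backend()].
#' @param parser parser backend, see [shallow_parser_backend()].
#' @return tibble of extracted entities with character spans `start`/`end`
#'   (0-based, end-exclusive, into `text`) where the phrase could be located.
#' @examples
#' ents <- extract_document("Babies need protein about 10 g a day.")
#' ents[, c("text", "entity_type", "label")]
#' @export
extract_document <- function(text, gazetteers = default_gazetteers(),
                             backend = builtin_annotation_backend(),
                             parser = shallow_parser_backend()) {
  sentences <- segment_sentences(text)
  out <- list()
  doc <- normalize_quotes(text)
  cursor <- 1L
  for (si in seq_along(sentences)) {
    sent_loc <- stringr::str_locate(substring(doc, cursor),
                                    stringr::fixed(sentences[si]))
    sent_off <- if (is.na(sent_loc[1])) NA_integer_ else cursor + sent_loc[1] - 1L
    if (!is.na(sent_off)) cursor <- sent_off + nchar(sentences[si]) - 1L
    res <- tryCatch({
      ann <- annotate_tokens(sentences[si], backend)
      segs <- split_into_segments(ann, sentence_index = si)
      do.call(rbind, c(list(empty_entities()),
                       lapply(segs, extract_segment,
                              gazetteers = gazetteers, parser = parser)))
    }, error = function(e) {
      warning(sprintf("sentence %d skipped: %s", si, conditionMessage(e)),
              call. = FALSE)
      empty_entities()
    })
    if (nrow(res) > 0) {
      span <- locate_spans(doc, sentences[si], sent_off, res$text)
      res$start <- span$start
      res$end <- span$end
    } else {
      res$start <- integer(0)
      res$end <- integer(0)
    }
    out[[length(out) + 1L]] <- res
  }
  if (length(out) == 0) {
    res <- empty_entities()
    res$start <- integer(0)
    res$end <- integer(0)
    return(res)
  }
  do.call(rbind, out)
}

# 0-based half-open character spans of entity phrases within the document.
# Tokens are matched in order, whitespace-flexibly; NA when not locatable
# (e.g. fixture tokenization differs from the raw text).
locate_spans <- function(doc, sentence, sent_off, phrases) {
  n <- length(phrases)
  start <- rep(NA_integer_, n)
  end <- rep(NA_integer_, n)
  if (is.na(sent_off)) return(list(start = start, end = end))
  for (i in seq_len(n)) {
    toks <- strsplit(phrases[i], " ", fixed = TRUE)[[1]]
    pat <- paste(vapply(toks, function(t) {
      gsub("([][.\\\\+*?^$(){}=!<>|:#-])", "\\\\\\1", t, perl = TRUE)
    }, character(1)), collapse = "\\s*")
    m <- regexpr(pat, substring(doc, sent_off), perl = TRUE, ignore.case = TRUE)
    if (m[1] != -1L) {
      start[i] <- sent_off + m[1] - 2L # 0-based
      end[i] <- start[i] + attr(m, "match.length")
    }
  }
  list(start = start, end = end)
}
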