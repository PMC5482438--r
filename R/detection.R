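#' Chunks of an annotated segment
#'
#' Groups a segment's B-I-O tags into chunks: each chunk is either one
#' phrase (a `B-` tag followed by its `I-` continuations) or a single
#' `O`-tagged token. Spans partition the tokens.
#'
#' @param segment an `annotated_sentence`.
#' @return a tibble with columns `index`, `phrase_type` (`"NP"`, `"VP"`, ...
#'   or `"O"`), `start`, `end` (token indices, inclusive) and `text`.
#' @export
segment_chunks <- function(segment) {
  stopifnot(inherits(segment, "annotated_sentence"))
  validate_chunk_tags(segment$chunk)
  bio <- substr(segment$chunk, 1, 1)
  starts <- which(bio %in% c("B", "O"))
  ends <- c(starts[-1] - 1L, nrow(segment))
  tibble::tibble(
    index = seq_along(starts),
    phrase_type = ifelse(segment$chunk[starts] == "O", "O",
                         chunk_phrase_type(segment$chunk[starts])),
    start = as.integer(starts),
    end = as.integer(ends),
    text = vapply(seq_along(starts), function(j) {
      paste(segment$token[starts[j]:ends[j]], collapse = " ")
    }, character(1))
  )
}

#' Token-by-chunk membership matrix
#'
#' Builds the n-token by m-chunk binary matrix whose entry (i, j) is 1 iff
#' token i belongs to chunk j; every row sums to exactly 1 because chunks
#' partition the tokens. Chunks are the spans of [segment_chunks()] (columns
#' count every tag beginning `B-` or `O`).
#'
#' @param segment an `annotated_sentence`.
#' @param chunks optional pre-computed chunk tibble (e.g. after post-hoc
#'   chunking); defaults to `segment_chunks(segment)`.
#' @return list with elements `matrix` (n x m, dimnames tokens x chunk
#'   texts) and `chunks` (the chunk tibble).
#' @examples
#' f <- system.file("extdata/fixtures/sodium_sentence.tsv", package = "dietner")
#' cm <- build_chunk_matrix(read_fixture_annotation(f))
#' dim(cm$matrix)
#' @export
build_chunk_matrix <- function(segment, chunks = NULL) {
  if (is.null(chunks)) chunks <- segment_chunks(segment)
  n <- nrow(segment)
  m <- nrow(chunks)
  x <- matrix(0L, n, m, dimnames = list(segment$token, chunks$text))
  for (j in seq_len(m)) {
    x[chunks$start[j]:chunks$end[j], j] <- 1L
  }
  list(matrix = x, chunks = chunks)
}

#' Token-by-entity dictionary membership matrix
#'
#' Builds the n-token by k-entity binary matrix whose entry (i, l) is 1 iff
#' token i belongs to dictionary l (any-vote over the gazetteer's sources).
#' Single-word terms are matched per token ([token_memberships()]);
#' multi-word terms match contiguous token runs, recording the hit on each
#' covered token.
#'
#' @param segment an `annotated_sentence`.
#' @param gazetteers ordered list of [gazetteer()]s.
#' @return n x k binary integer matrix, columns named by entity type.
#' @export
build_dictionary_matrix <- function(segment, gazetteers) {
  n <- nrow(segment)
  k <- length(gazetteers)
  types <- vapply(gazetteers, `[[`, character(1), "entity_type")
  x <- matrix(0L, n, k, dimnames = list(segment$token, types))
  if (k == 0 || n == 0) return(x)
  low <- tolower(segment$token)
  for (l in seq_len(k)) {
    g <- gazetteers[[l]]
    for (i in seq_len(n)) {
      if (single_token_member(segment$token[i], g)) x[i, l] <- 1L
    }
    for (words in g$multiword) {
      w <- length(words)
      if (w > n) next
      target <- tolower(words)
      cased <- any(grepl("[A-Z]", words))
      for (i in seq_len(n - w + 1)) {
        span <- i:(i + w - 1)
        hit <- if (cased) all(segment$token[span] == words) else all(low[span] == target)
        if (hit) x[span, l] <- 1L
      }
    }
  }
  x
}

#' Chunk-by-entity mention matrix
#'
#' The matrix product `t(chunk_matrix) %*% dict_matrix`: entry (j, l) counts
#' the dictionary-l tokens inside chunk j. A chunk with any entry >= 1 is an
#' entity mention; a chunk with evidence for more than one type obtains its
#' resolved tag from its last dictionary-hit token (ties on one token go to
#' the earliest entity type in column order).
#'
#' @param chunk_matrix result of [build_chunk_matrix()] (the list or the bare
#'   matrix).
#' @param dict_matrix result of [build_dictionary_matrix()].
#' @return an object of class `entity_matrix`: the m x k integer matrix with
#'   attributes `flags` (binary m x k) and `resolved` (length-m character,
#'   `NA` for non-mentions).
#' @export
build_entity_matrix <- function(chunk_matrix, dict_matrix) {
  x_chunks <- if (is.list(chunk_matrix)) chunk_matrix$matrix else chunk_matrix
  if (nrow(x_chunks) != nrow(dict_matrix)) {
    stop(sprintf("dimension mismatch: %d tokens in chunk matrix vs %d in dictionary matrix",
                 nrow(x_chunks), nrow(dict_matrix)))
  }
  ents <- t(x_chunks) %*% dict_matrix
  storage.mode(ents) <- "integer"
  flags <- (ents >= 1L) * 1L
  resolved <- rep(NA_character_, nrow(ents))
  for (j in seq_len(nrow(ents))) {
    toks <- which(x_chunks[, j] == 1L)
    hits <- toks[rowSums(dict_matrix[toks, , drop = FALSE]) > 0]
    if (length(hits) == 0) next
    last <- max(hits)
    resolved[j] <- colnames(dict_matrix)[which(dict_matrix[last, ] == 1L)[1]]
  }
  structure(ents, flags = flags, resolved = resolved, class = c("entity_matrix", "matrix", "array"))
}

#' @export
print.entity_matrix <- function(x, ...) {
  cat(sprintf("<entity_matrix> %d chunks x %d entity types\n", nrow(x), ncol(x)))
  print(unclass(x)[, , drop = FALSE], ...)
  invisible(x)
}

# Resolved one-hot label vector for one chunk span, computed from the
# dictionary matrix (used to refresh labels as chunks merge).
resolved_label_vector <- function(start, end, dict_matrix) {
  k <- ncol(dict_matrix)
  out <- integer(k)
  names(out) <- colnames(dict_matrix)
  span <- start:end
  hits <- span[rowSums(dict_matrix[span, , drop = FALSE]) > 0]
  if (length(hits) == 0) return(out)
  last <- max(hits)
  out[which(dict_matrix[last, ] == 1L)[1]] <- 1L
  out
}

resolved_label <- function(start, end, dict_matrix) {
  v <- resolved_label_vector(start, end, dict_matrix)
  if (any(v == 1L)) names(v)[v == 1L] else NA_character_
}

#' Boolean merge guard
#'
#' Decides whether merging two labeled chunks is information-safe: the merge
#' is forbidden exactly when the outer chunks carry labels of two different
#' entity types, because fusing them would lose one mention. Formally the
#' guard is the conjunction of `!(A & B)` over all ordered pairs of distinct
#' entity types — `V(k, 2) = k! / (k - 2)!` pairwise functions — which
#' reduces to: true iff no pair of distinct types is flagged on opposite
#' sides.
#'
#' @param outer_left,outer_right binary label vectors of equal length k
#'   (one flag per entity type).
#' @return `TRUE` when merging is allowed.
#' @examples
#' merge_guard(c(0, 1, 0), c(0, 0, 1)) # Nutrient vs Quantity/Unit: forbidden
#' merge_guard(c(0, 0, 0), c(0, 0, 0)) # nothing at stake: allowed
#' @export
merge_guard <- function(outer_left, outer_right) {
  if (length(outer_left) != length(outer_right)) {
    stop("merge_guard: label vectors must have equal length")
  }
  k <- length(outer_left)
  for (e1 in seq_len(k)) {
    for (e2 in seq_len(k)) {
      if (e1 != e2 && outer_left[e1] == 1 && outer_right[e2] == 1) return(FALSE)
    }
  }
  TRUE
}

#' Number of pairwise guard functions
#'
#' Variations without repetition `V(r, w) = r! / (r - w)!`: with `k` entity
#' types the merge guard is a conjunction of `V(k, 2)` pairwise Boolean
#' functions.
#'
#' @param r number of distinct elements (entity types).
#' @param w size of the variation (2 for pairs).
#' @return integer count.
#' @examples
#' variations_without_repetition(3, 2) # 6
#' @export
variations_without_repetition <- function(r, w = 2) {
  stopifnot(r >= w)
  as.integer(round(factorial(r) / factorial(r - w)))
}

# Merge chunks[i..(i+span-1)] into one NP chunk.
merge_chunk_rows <- function(chunks, i, span, segment) {
  left <- chunks[i, ]
  right <- chunks[i + span - 1, ]
  merged <- tibble::tibble(
    index = left$index,
    phrase_type = "NP",
    start = left$start,
    end = right$end,
    text = paste(segment$token[left$start:right$end], collapse = " ")
  )
  out <- rbind(chunks[seq_len(i - 1), ], merged,
               chunks[seq_len(nrow(chunks)) > i + span - 1, ])
  out$index <- seq_len(nrow(out))
  out
}

#' First post-hoc chunking: guarded (NP, PP, NP) trigram merges
#'
#' Scans successive chunk trigrams left to right; a trigram shaped
#' (NP, PP, NP) whose outer chunks pass [merge_guard()] (on their resolved
#' labels) is merged into one noun chunk. After a merge the scan resumes with
#' the merged chunk as the left element, so merges can chain into long
#' phrases ("the recommended intake" + "for" + "total fiber" + "for" +
#' "adults").
#'
#' @param chunks chunk tibble (from [segment_chunks()]).
#' @param dict_matrix token-by-entity matrix of the same segment, used to
#'   refresh chunk labels as merges happen.
#' @param segment the `annotated_sentence` the chunks index into.
#' @return the merged chunk tibble, with attribute `n_candidates` — the
#'   number of (NP, PP, NP) trigrams examined.
#' @export
posthoc_chunking_1 <- function(chunks, dict_matrix, segment) {
  n_candidates <- count_trigrams(chunks, c("NP", "PP", "NP"))
  i <- 1L
  while (i + 2 <= nrow(chunks)) {
    shape <- chunks$phrase_type[i:(i + 2)]
    if (identical(shape, c("NP", "PP", "NP"))) {
      left <- resolved_label_vector(chunks$start[i], chunks$end[i], dict_matrix)
      right <- resolved_label_vector(chunks$start[i + 2], chunks$end[i + 2], dict_matrix)
      if (merge_guard(left, right)) {
        chunks <- merge_chunk_rows(chunks, i, 3L, segment)
        next # resume with the merged chunk as the left element
      }
    }
    i <- i + 1L
  }
  attr(chunks, "n_candidates") <- n_candidates
  chunks
}

# Trigram candidates are counted on the incoming chunk sequence, before any
# merge rewrites it.
count_trigrams <- function(chunks, shape) {
  m <- nrow(chunks)
  if (m < 3) return(0L)
  sum(vapply(seq_len(m - 2), function(i) {
    identical(chunks$phrase_type[i:(i + 2)], shape)
  }, logical(1)))
}

#' Second post-hoc chunking: wh-pronoun (NP, VP, NP) trigram merges
#'
#' Merges a trigram shaped (NP, VP, NP) into one noun chunk when the first
#' noun chunk contains a wh-pronoun POS tag (WP, WP$, WDT) — fusing relative
#' clauses like "who are African Americans" into a single phrase.
#'
#' @inheritParams posthoc_chunking_1
#' @return merged chunk tibble with attribute `n_candidates` — the number of
#'   (NP, VP, NP) trigrams examined.
#' @export
posthoc_chunking_2 <- function(chunks, segment) {
  n_candidates <- count_trigrams(chunks, c("NP", "VP", "NP"))
  i <- 1L
  while (i + 2 <= nrow(chunks)) {
    shape <- chunks$phrase_type[i:(i + 2)]
    if (identical(shape, c("NP", "VP", "NP"))) {
      wh <- any(segment$pos[chunks$start[i]:chunks$end[i]] %in% WH_TAGS)
      if (wh) {
        chunks <- merge_chunk_rows(chunks, i, 3L, segment)
        i <- i + 1L # a merged relative clause does not seed further merges
        next
      }
    }
    i <- i + 1L
  }
  attr(chunks, "n_candidates") <- n_candidates
  chunks
}

#' Third post-hoc chunking: (NP, NP) bigram merges on compatible labels
#'
#' Merges a bigram of successive noun chunks when exactly one of them is
#' labeled as an entity of interest, or both carry the same label. Bigrams
#' with two different entity labels — or with neither chunk labeled — are
#' untouched.
#'
#' @inheritParams posthoc_chunking_1
#' @return merged chunk tibble.
#' @export
posthoc_chunking_3 <- function(chunks, dict_matrix, segment) {
  i <- 1L
  while (i + 1 <= nrow(chunks)) {
    if (chunks$phrase_type[i] == "NP" && chunks$phrase_type[i + 1] == "NP") {
      a <- resolved_label(chunks$start[i], chunks$end[i], dict_matrix)
      b <- resolved_label(chunks$start[i + 1], chunks$end[i + 1], dict_matrix)
      one_labeled <- xor(is.na(a), is.na(b))
      same_label <- !is.na(a) && !is.na(b) && a == b
      if (one_labeled || same_label) {
        chunks <- merge_chunk_rows(chunks, i, 2L, segment)
        next
      }
    }
    i <- i + 1L
  }
  chunks
}

#' Recalculate the entity matrix over merged chunks
#'
#' After the three post-hoc chunkings the chunk inventory changed, so the
#' token-by-chunk and chunk-by-entity matrices are rebuilt. The recalculated
#' matrix keeps phrase chunks only: `O`-tagged outside-chunk tokens are
#' excluded from its rows.
#'
#' @param segment the `annotated_sentence`.
#' @param chunks merged chunk tibble.
#' @param gazetteers ordered list of [gazetteer()]s (or a pre-computed
#'   dictionary matrix via `dict_matrix`).
#' @param dict_matrix optional pre-computed token-by-entity matrix.
#' @return list with `chunks` (phrase chunks only), `entity` (the
#'   recalculated `entity_matrix`) and `dict_matrix`.
#' @export
recalculate_entities <- function(segment, chunks, gazetteers = NULL,
                                 dict_matrix = NULL) {
  if (is.null(dict_matrix)) {
    stopifnot(!is.null(gazetteers))
    dict_matrix <- build_dictionary_matrix(segment, gazetteers)
  }
  phrase <- chunks[chunks$phrase_type != "O", , drop = FALSE]
  phrase$index <- seq_len(nrow(phrase))
  if (nrow(phrase) == 0) {
    ents <- structure(matrix(0L, 0, ncol(dict_matrix),
                             dimnames = list(NULL, colnames(dict_matrix))),
                      flags = matrix(0L, 0, ncol(dict_matrix)),
                      resolved = character(0),
                      class = c("entity_matrix", "matrix", "array"))
    return(list(chunks = phrase, entity = ents, dict_matrix = dict_matrix))
  }
  x <- matrix(0L, nrow(segment), nrow(phrase),
              dimnames = list(segment$token, phrase$text))
  for (j in seq_len(nrow(phrase))) x[phrase$start[j]:phrase$end[j], j] <- 1L
  ents <- build_entity_matrix(x, dict_matrix)
  list(chunks = phrase, entity = ents, dict_matrix = dict_matrix)
}

#' Run phase one on a segment
#'
#' Convenience wrapper: initial chunk/dictionary/entity matrices, the three
#' post-hoc chunkings, and the recalculated entity matrix.
#'
#' @param segment an `annotated_sentence` (typically from
#'   [split_into_segments()]).
#' @param gazetteers ordered list of [gazetteer()]s.
#' @return list with `initial` (chunks + `entity_matrix` including O rows),
#'   `merged_chunks` (all chunks after the three passes, O chunks included),
#'   `recalc` (see [recalculate_entities()]), `dict_matrix`, and the trigram
#'   candidate counts `n_trigrams_1`, `n_trigrams_2`.
#' @export
detect_mentions <- function(segment, gazetteers) {
  cm <- build_chunk_matrix(segment)
  dm <- build_dictionary_matrix(segment, gazetteers)
  ents0 <- build_entity_matrix(cm, dm)
  ch1 <- posthoc_chunking_1(cm$chunks, dm, segment)
  ch2 <- posthoc_chunking_2(ch1, segment)
  ch3 <- posthoc_chunking_3(ch2, dm, segment)
  recalc <- recalculate_entities(segment, ch3, dict_matrix = dm)
  list(
    initial = list(chunks = cm$chunks, entity = ents0),
    merged_chunks = ch3,
    recalc = recalc,
    dict_matrix = dm,
    n_trigrams_1 = attr(ch1, "n_candidates"),
    n_trigrams_2 = attr(ch2, "n_candidates")
  )
}
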