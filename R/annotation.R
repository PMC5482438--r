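#' Construct an annotated sentence
#'
#' An `annotated_sentence` is a tibble with one row per token and columns
#' `index`, `token`, `lemma`, `pos` (Penn-Treebank tag) and `chunk` (B-I-O
#' chunk tag such as `"B-NP"`, `"I-VP"` or `"O"`), with the original sentence
#' text kept as an attribute. It is the unit everything downstream operates
#' on; sentence segments are annotated sentences with `sentence_index` and
#' `segment_index` attributes.
#'
#' Validation enforces the B-I-O contract: an `O` tag carries no phrase type,
#' and an `I-` tag must continue a chunk of the same phrase type (a dangling
#' `I` is an annotation error).
#'
#' @param token,pos,chunk aligned character vectors.
#' @param text original sentence string (defaults to the joined tokens).
#' @param lemma optional lemmas; computed with [lemma()] when missing.
#' @param start,end optional character offsets of each token within `text`.
#' @return an `annotated_sentence`.
#' @examples
#' new_annotated_sentence(c("Eat", "."), c("VB", "."), c("B-VP", "O"))
#' @export
new_annotated_sentence <- function(token, pos, chunk, text = NULL,
                                   lemma = NULL, start = NULL, end = NULL) {
  stopifnot(length(token) == length(pos), length(token) == length(chunk))
  if (any(!nzchar(token))) stop("tokens must be non-empty strings")
  validate_chunk_tags(chunk)
  if (is.null(lemma)) lemma <- dietner::lemma(token)
  ann <- tibble::tibble(
    index = seq_along(token),
    token = as.character(token),
    lemma = as.character(lemma),
    pos = as.character(pos),
    chunk = as.character(chunk)
  )
  if (!is.null(start)) {
    ann$start <- as.integer(start)
    ann$end <- as.integer(end)
  }
  if (is.null(text)) text <- paste(token, collapse = " ")
  structure(ann, text = text,
            class = c("annotated_sentence", class(ann)))
}

validate_chunk_tags <- function(chunk) {
  ok <- chunk == "O" | grepl("^[BI]-[A-Z]+$", chunk)
  if (any(!ok)) {
    stop(sprintf("malformed chunk tag(s): %s",
                 paste(unique(chunk[!ok]), collapse = ", ")))
  }
  ptype <- chunk_phrase_type(chunk)
  bad <- ptype != "" & !(ptype %in% PHRASE_TYPES)
  if (any(bad)) {
    stop(sprintf("unknown phrase type(s): %s",
                 paste(unique(ptype[bad]), collapse = ", ")))
  }
  bio <- substr(chunk, 1, 1)
  for (i in seq_along(chunk)) {
    if (bio[i] == "I") {
      if (i == 1 || bio[i - 1] == "O" || ptype[i - 1] != ptype[i]) {
        stop(sprintf("dangling I tag at token %d (%s)", i, chunk[i]))
      }
    }
  }
  invisible(chunk)
}

chunk_phrase_type <- function(chunk) {
  ifelse(chunk == "O", "", sub("^[BI]-", "", chunk))
}

#' @export
print.annotated_sentence <- function(x, ...) {
  cat("<annotated_sentence> ", attr(x, "text"), "\n", sep = "")
  si <- attr(x, "sentence_index")
  if (!is.null(si)) {
    cat(sprintf("  sentence %d, segment %d\n", si, attr(x, "segment_index")))
  }
  NextMethod()
}

#' Split a document into sentences
#'
#' Splits plain text on sentence-final punctuation (`.`, `!`, `?`, optionally
#' followed by a closing quote or bracket) when followed by whitespace and an
#' upper-case letter, digit or opening quote, and on blank lines. Empty input
#' yields an empty character vector.
#'
#' @param document_text a length-1 character string (UTF-8).
#' @return character vector of sentence strings, in document order.
#' @examples
#' segment_sentences("Babies need protein. Eat fiber daily.")
#' @export
segment_sentences <- function(document_text) {
  stopifnot(is.character(document_text), length(document_text) == 1)
  text <- normalize_quotes(document_text)
  if (!nzchar(trimws(text))) return(character(0))
  # Paragraph breaks are hard boundaries.
  paras <- unlist(strsplit(text, "\n[ \t]*\n+"))
  out <- character(0)
  boundary <- "(?<=[.!?][\"')\\]]?)\\s+(?=[\"'(\\[]?[A-Z0-9])"
  for (p in paras) {
    p <- gsub("\\s+", " ", trimws(p))
    if (!nzchar(p)) next
    out <- c(out, unlist(strsplit(p, boundary, perl = TRUE)))
  }
  out[nzchar(trimws(out))]
}

#' Annotate one sentence with a backend
#'
#' Runs the backend's tokenizer, POS tagger and chunker on a sentence and
#' returns the aligned annotation. Deterministic for a fixed backend.
#'
#' @param sentence a sentence string.
#' @param backend a `dietner_backend`, see [builtin_annotation_backend()].
#' @return an [new_annotated_sentence()] object.
#' @export
annotate_tokens <- function(sentence, backend = builtin_annotation_backend()) {
  stopifnot(inherits(backend, "dietner_backend"))
  ann <- backend$annotate(sentence)
  if (!inherits(ann, "annotated_sentence")) {
    stop(backend_error("backend did not return an annotated_sentence"))
  }
  ann
}

#' Read or write a fixture annotation file
#'
#' Fixture files carry a pre-computed annotation: tab-separated, header row
#' `Token	POS	Chunk`, one token per line, `#` comment lines allowed. They make
#' every downstream step reproducible without any tagger.
#'
#' @param path file path.
#' @param text optional original sentence text; defaults to the joined tokens.
#' @return `read_fixture_annotation()` returns an `annotated_sentence`;
#'   `write_fixture_annotation()` returns `path` invisibly.
#' @examples
#' f <- system.file("extdata/fixtures/sodium_sentence.tsv", package = "dietner")
#' ann <- read_fixture_annotation(f)
#' nrow(ann)
#' @export
read_fixture_annotation <- function(path, text = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  rows <- which(keep)
  lines <- lines[keep]
  if (length(lines) < 1) stop(sprintf("fixture file %s is empty", path))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ncols <- lengths(fields)
  if (any(ncols != 3)) {
    bad <- which(ncols != 3)[1]
    stop(sprintf("fixture file %s: expected 3 tab-separated columns but found %d on line %d",
                 path, ncols[bad], rows[bad]))
  }
  header <- fields[[1]]
  if (!identical(tolower(header), c("token", "pos", "chunk"))) {
    stop(sprintf("fixture file %s: header must be Token/POS/Chunk", path))
  }
  fields <- fields[-1]
  tok <- vapply(fields, `[[`, character(1), 1)
  pos <- vapply(fields, `[[`, character(1), 2)
  chk <- vapply(fields, `[[`, character(1), 3)
  new_annotated_sentence(tok, pos, chk, text = text)
}

#' @rdname read_fixture_annotation
#' @param ann an `annotated_sentence`.
#' @export
write_fixture_annotation <- function(ann, path) {
  stopifnot(inherits(ann, "annotated_sentence"))
  lines <- c("Token\tPOS\tChunk",
             paste(ann$token, ann$pos, ann$chunk, sep = "\t"))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Split an annotated sentence into segments
#'
#' A sentence is split wherever the chunking produced an `ADVP`, `CONJP` or
#' `SBAR` chunk, or two successive `O`-tagged tokens. The trigger chunk's
#' tokens are removed; `O`-tagged punctuation adjacent to a split point is
#' dropped, other `O` tokens stay with the following segment. Double quotation
#' marks and brackets are removed from every segment. Segments are numbered
#' `1..s` in order of appearance; the number becomes the subscript of the
#' S/P/O labels.
#'
#' @param sentence an `annotated_sentence`.
#' @param sentence_index 1-based index of the sentence in its document.
#' @return list of segments (annotated sentences with `sentence_index` and
#'   `segment_index` attributes).
#' @examples
#' f <- system.file("extdata/fixtures/fiber_sentence.tsv", package = "dietner")
#' segs <- split_into_segments(read_fixture_annotation(f))
#' length(segs)
#' @export
split_into_segments <- function(sentence, sentence_index = 1L) {
  stopifnot(inherits(sentence, "annotated_sentence"))
  n <- nrow(sentence)
  if (n == 0) return(list())
  ptype <- chunk_phrase_type(sentence$chunk)
  bio <- substr(sentence$chunk, 1, 1)

  # Per-token disposition: "keep", "trigger" (removed ADVP/CONJP/SBAR chunk),
  # plus a logical marking tokens that open a new segment.
  trigger <- ptype %in% c("ADVP", "CONJP", "SBAR")
  # Boundary before the first O of each (O,O) run, and between every two
  # successive O tokens, so no emitted segment can retain an (O,O) pair.
  opens <- logical(n)
  is_o <- sentence$chunk == "O"
  for (i in seq_len(n)) {
    if (!is_o[i]) next
    if (i > 1 && is_o[i - 1]) {
      opens[i] <- TRUE
    } else if (i < n && is_o[i + 1]) {
      opens[i] <- TRUE
    }
  }

  # Assign each kept token a raw segment id.
  seg_id <- integer(n)
  cur <- 1L
  prev_trigger <- FALSE
  for (i in seq_len(n)) {
    if (trigger[i]) {
      prev_trigger <- TRUE
      seg_id[i] <- NA_integer_
      next
    }
    if ((opens[i] || prev_trigger) && any(seg_id[seq_len(i - 1)] > 0, na.rm = TRUE)) {
      cur <- cur + 1L
    }
    prev_trigger <- FALSE
    seg_id[i] <- cur
  }

  # Drop O punctuation adjacent to a split point (first/last token of a
  # segment that is not also the sentence boundary punctuation pattern is
  # kept; only boundary-adjacent punctuation between different segments or
  # next to a removed trigger goes).
  punct <- sentence$chunk == "O" & is_punct_token(sentence$token)
  drop <- logical(n)
  for (i in seq_len(n)) {
    if (!punct[i] || is.na(seg_id[i])) next
    prev_id <- if (i > 1) seg_id[i - 1] else NA_integer_
    next_id <- if (i < n) seg_id[i + 1] else NA_integer_
    at_boundary <- (i > 1 && (is.na(prev_id) || prev_id != seg_id[i])) ||
      (i < n && (is.na(next_id) || next_id != seg_id[i]))
    if (at_boundary) drop[i] <- TRUE
  }
  # Quotation marks and brackets are removed everywhere.
  drop <- drop | (sentence$token %in% c("\"", "(", ")", "[", "]", "{", "}",
                                        "``", "''"))
  seg_id[drop] <- NA_integer_

  ids <- unique(seg_id[!is.na(seg_id)])
  segs <- vector("list", length(ids))
  for (s in seq_along(ids)) {
    idx <- which(!is.na(seg_id) & seg_id == ids[s])
    seg <- sentence[idx, , drop = FALSE]
    seg$index <- seq_len(nrow(seg))
    # A chunk cut at a segment boundary may now start with an I- tag; promote
    # it to B- so the segment is a valid annotation on its own.
    bio_s <- substr(seg$chunk, 1, 1)
    pt_s <- chunk_phrase_type(seg$chunk)
    for (j in seq_len(nrow(seg))) {
      if (bio_s[j] == "I" &&
          (j == 1 || bio_s[j - 1] == "O" || pt_s[j - 1] != pt_s[j])) {
        seg$chunk[j] <- paste0("B-", pt_s[j])
        bio_s[j] <- "B"
      }
    }
    seg <- new_annotated_sentence(seg$token, seg$pos, seg$chunk,
                                  text = paste(seg$token, collapse = " "),
                                  lemma = seg$lemma)
    attr(seg, "sentence_index") <- as.integer(sentence_index)
    attr(seg, "segment_index") <- s
    attr(seg, "parent_text") <- attr(sentence, "text")
    segs[[s]] <- seg
  }
  segs
}
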