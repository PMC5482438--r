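#' Constituency parse trees
#'
#' A parse node is a list with a `label` (constituency or POS tag), ordered
#' `children`, and — for leaves — the surface `token` and its 1-based token
#' `index` in the segment. Two sources are supported:
#'
#' * [read_parse_tree()] parses Penn-style bracketed notation, e.g.
#'   `"(S (NP (NN Eat)) (. .))"`, assigning leaf indices in reading order.
#' * [shallow_parse_tree()] builds a two-level tree from a segment's (merged)
#'   chunk sequence: the root `S` has one child per chunk, labeled with the
#'   chunk's phrase type, whose children are POS preterminals over the
#'   tokens. Because merged chunks absorb embedded material (a relative
#'   clause fused into an NP hides its inner verb), predicate search over
#'   this tree reproduces the behaviour of a full parser on typical
#'   recommendation sentences.
#'
#' @param text bracketed tree string.
#' @return a `parse_node`.
#' @examples
#' tr <- read_parse_tree("(S (NP (NNS Babies)) (VP (VBP need) (NP (NN protein))) (. .))")
#' parse_leaves(tr)$token
#' @export
read_parse_tree <- function(text) {
  toks <- regmatches(text, gregexpr("\\(|\\)|[^()\\s]+", text, perl = TRUE))[[1]]
  pos <- 1L
  idx_counter <- 0L
  parse_node <- function() {
    if (toks[pos] != "(") stop("parse error: expected '('")
    pos <<- pos + 1L
    label <- toks[pos]
    pos <<- pos + 1L
    children <- list()
    token <- NULL
    index <- NULL
    while (pos <= length(toks) && toks[pos] != ")") {
      if (toks[pos] == "(") {
        children[[length(children) + 1L]] <- parse_node()
      } else {
        token <- toks[pos]
        idx_counter <<- idx_counter + 1L
        index <- idx_counter
        pos <<- pos + 1L
      }
    }
    if (pos > length(toks)) stop("parse error: unbalanced brackets")
    pos <<- pos + 1L
    structure(list(label = label, children = children,
                   token = token, index = index),
              class = "parse_node")
  }
  node <- parse_node()
  if (pos <= length(toks)) stop("parse error: trailing content")
  node
}

#' @rdname read_parse_tree
#' @param segment an `annotated_sentence`.
#' @param chunks chunk tibble (typically the merged chunks of phase one).
#' @export
shallow_parse_tree <- function(segment, chunks = segment_chunks(segment)) {
  preterminal <- function(i) {
    structure(list(label = segment$pos[i], children = list(),
                   token = segment$token[i], index = i),
              class = "parse_node")
  }
  kids <- lapply(seq_len(nrow(chunks)), function(j) {
    span <- chunks$start[j]:chunks$end[j]
    if (chunks$phrase_type[j] == "O") {
      preterminal(span[1])
    } else {
      structure(list(label = chunks$phrase_type[j],
                     children = lapply(span, preterminal),
                     token = NULL, index = NULL),
                class = "parse_node")
    }
  })
  structure(list(label = "S", children = kids, token = NULL, index = NULL),
            class = "parse_node")
}

#' @export
print.parse_node <- function(x, ...) {
  fmt <- function(n) {
    if (length(n$children) == 0 && !is.null(n$token)) {
      sprintf("(%s %s)", n$label, n$token)
    } else {
      sprintf("(%s %s)", n$label, paste(vapply(n$children, fmt, character(1)),
                                        collapse = " "))
    }
  }
  cat(fmt(x), "\n")
  invisible(x)
}

#' @rdname read_parse_tree
#' @param tree a `parse_node`.
#' @export
parse_leaves <- function(tree) {
  out <- list()
  walk <- function(node, depth) {
    if (length(node$children) == 0 && !is.null(node$token)) {
      out[[length(out) + 1L]] <<- list(token = node$token, index = node$index,
                                       pos = node$label, depth = depth)
    } else {
      for (ch in node$children) walk(ch, depth + 1L)
    }
  }
  walk(tree, 0L)
  tibble::tibble(
    token = vapply(out, `[[`, character(1), "token"),
    index = vapply(out, function(l) as.integer(l$index), integer(1)),
    pos = vapply(out, `[[`, character(1), "pos"),
    depth = vapply(out, function(l) as.integer(l$depth), integer(1))
  )
}

# Verb-leaf candidates with the depth of their shallowest enclosing VP.
# Returns a tibble ordered as encountered (reading order).
verb_candidates <- function(tree) {
  out <- list()
  walk <- function(node, depth, vp_depth) {
    if (identical(substr(node$label, 1, 2), "VP")) {
      if (is.na(vp_depth)) vp_depth <- depth
    }
    if (length(node$children) == 0 && !is.null(node$token)) {
      if (node$label %in% VERB_TAGS && !is.na(vp_depth)) {
        out[[length(out) + 1L]] <<- list(index = node$index, depth = depth,
                                         vp_depth = vp_depth, pos = node$label)
      }
      return(invisible())
    }
    for (ch in node$children) walk(ch, depth + 1L, vp_depth)
  }
  walk(tree, 0L, NA_integer_)
  tibble::tibble(
    index = vapply(out, function(l) as.integer(l$index), integer(1)),
    depth = vapply(out, function(l) as.integer(l$depth), integer(1)),
    vp_depth = vapply(out, function(l) as.integer(l$vp_depth), integer(1)),
    pos = vapply(out, `[[`, character(1), "pos")
  )
}

#' Parser backends
#'
#' A parser backend maps a segment (plus its merged chunks) to a
#' constituency tree. `shallow_parser_backend()` uses [shallow_parse_tree()];
#' `fixture_parser_backend()` replays bundled bracketed trees matched by
#' normalized sentence text, consulting `fallback` on a miss.
#'
#' @param trees named list: normalized-text-keyed bracketed strings or
#'   `parse_node` objects. Keys are matched after lower-casing and stripping
#'   non-alphanumerics.
#' @param fallback backend used when no fixture matches (default: shallow).
#' @return object of class `dietner_parser`: list with a `parse` function
#'   `(segment, chunks) -> parse_node` and a `name`.
#' @export
shallow_parser_backend <- function() {
  structure(list(name = "shallow",
                 parse = function(segment, chunks) shallow_parse_tree(segment, chunks)),
            class = "dietner_parser")
}

#' @rdname shallow_parser_backend
#' @export
fixture_parser_backend <- function(trees, fallback = shallow_parser_backend()) {
  keys <- vapply(names(trees), normalize_sentence_key, character(1))
  trees <- lapply(trees, function(t) if (inherits(t, "parse_node")) t else read_parse_tree(t))
  structure(
    list(
      name = "fixture",
      parse = function(segment, chunks) {
        key <- normalize_sentence_key(paste(segment$token, collapse = " "))
        hit <- match(key, keys)
        if (!is.na(hit)) return(trees[[hit]])
        if (is.null(fallback)) stop(backend_error("no fixture parse for segment"))
        fallback$parse(segment, chunks)
      }
    ),
    class = "dietner_parser"
  )
}
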