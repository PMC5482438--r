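#' Write extracted entities
#'
#' Serializes an entity tibble (from [extract_document()]) to one of three
#' formats:
#'
#' * `"jsonl"` — one JSON object per entity with fields `text`, `type`,
#'   `spo`, `label`, `sentence_index`, `segment_index`, `start`, `end`.
#' * `"tsv"` — the same columns, tab-separated with a header (an empty
#'   entity list yields a header-only file).
#' * `"brat"` — BRAT standoff `.ann`: `T` lines for entity spans (offsets
#'   0-based, end-exclusive, into the original document text) and `A`
#'   attribute lines carrying the S/P/O value. Entities without a locatable
#'   span are skipped in BRAT output.
#'
#' `jsonl` and `tsv` are lossless: [read_entities()] reproduces the tibble.
#'
#' @param entities entity tibble.
#' @param path destination file.
#' @param format one of `"jsonl"`, `"tsv"`, `"brat"`.
#' @return `path`, invisibly.
#' @export
write_entities <- function(entities, path, format = c("jsonl", "tsv", "brat")) {
  format <- match.arg(format)
  ent <- as.data.frame(entities)
  if (!"start" %in% names(ent)) {
    ent$start <- NA_integer_
    ent$end <- NA_integer_
  }
  cols <- c("text", "entity_type", "spo", "label", "sentence_index",
            "segment_index", "start", "end")
  ent <- ent[, cols, drop = FALSE]
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  if (format == "jsonl") {
    if (nrow(ent) > 0) {
      for (i in seq_len(nrow(ent))) {
        writeLines(jsonlite::toJSON(as.list(ent[i, , drop = FALSE]),
                                    auto_unbox = TRUE, na = "null"), con)
      }
    }
  } else if (format == "tsv") {
    writeLines(paste(cols, collapse = "\t"), con)
    if (nrow(ent) > 0) {
      lines <- apply(ent, 1, function(r) paste(ifelse(is.na(r), "", trimws(r)),
                                               collapse = "\t"))
      writeLines(lines, con)
    }
  } else {
    tid <- 0L
    for (i in seq_len(nrow(ent))) {
      if (is.na(ent$start[i])) next
      tid <- tid + 1L
      writeLines(sprintf("T%d\t%s %d %d\t%s", tid, ent$entity_type[i],
                         ent$start[i], ent$end[i], ent$text[i]), con)
      writeLines(sprintf("A%d\tSPO T%d %s", tid, tid, ent$spo[i]), con)
    }
  }
  invisible(path)
}

#' @rdname write_entities
#' @export
read_entities <- function(path, format = c("jsonl", "tsv")) {
  format <- match.arg(format)
  if (format == "jsonl") {
    lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
    lines <- lines[nzchar(lines)]
    if (length(lines) == 0) return(entity_io_empty())
    rows <- lapply(lines, function(l) jsonlite::fromJSON(l))
    out <- tibble::tibble(
      text = vapply(rows, function(r) as.character(r$text), character(1)),
      entity_type = vapply(rows, function(r) as.character(r$entity_type), character(1)),
      spo = vapply(rows, function(r) as.character(r$spo), character(1)),
      label = vapply(rows, function(r) as.character(r$label), character(1)),
      sentence_index = vapply(rows, function(r) as.integer(r$sentence_index), integer(1)),
      segment_index = vapply(rows, function(r) as.integer(r$segment_index), integer(1)),
      start = vapply(rows, function(r) if (is.null(r$start)) NA_integer_ else as.integer(r$start), integer(1)),
      end = vapply(rows, function(r) if (is.null(r$end)) NA_integer_ else as.integer(r$end), integer(1))
    )
    return(out)
  }
  df <- utils::read.delim(path, sep = "\t", quote = "", stringsAsFactors = FALSE,
                          colClasses = "character", check.names = FALSE,
                          na.strings = NULL)
  if (nrow(df) == 0) return(entity_io_empty())
  tibble::tibble(
    text = df$text, entity_type = df$entity_type, spo = df$spo,
    label = df$label,
    sentence_index = as.integer(df$sentence_index),
    segment_index = as.integer(df$segment_index),
    start = suppressWarnings(as.integer(df$start)),
    end = suppressWarnings(as.integer(df$end))
  )
}

entity_io_empty <- function() {
  tibble::tibble(text = character(0), entity_type = character(0),
                 spo = character(0), label = character(0),
                 sentence_index = integer(0), segment_index = integer(0),
                 start = integer(0), end = integer(0))
}

#' Command-line driver
#'
#' Runs [extract_document()] over one or more plain-text input files and
#' writes one output file per input (input path plus an extension-dependent
#' suffix, or `--output` for a single input). Flags:
#'
#' * `--input PATH` (repeatable) — plain-text document(s) to process.
#' * `--lexicon-dir DIR` — directory with `food.tsv`, `nutrient.tsv`,
#'   `unit.tsv` (default: bundled lexicons).
#' * `--format {json,tsv,brat}` — output format (default `json`, written as
#'   JSON lines).
#' * `--fixture-annotations DIR` — directory of fixture TSVs; sentences with
#'   a matching fixture use it, others fall back to the built-in backend.
#' * `--output PATH` — output file (single input only).
#' * `--log-level {quiet,info}` — `info` reports per-sentence segment and
#'   entity counts.
#'
#' @param argv character vector of command-line arguments.
#' @return integer exit status: 0 on success, 2 on a usage/configuration
#'   error.
#' @export
cli_main <- function(argv = commandArgs(trailingOnly = TRUE)) {
  usage <- paste(
    "usage: dietner --input FILE [--input FILE ...] [--lexicon-dir DIR]",
    "               [--format json|tsv|brat] [--fixture-annotations DIR]",
    "               [--output FILE] [--log-level quiet|info]", sep = "\n")
  opts <- list(input = character(0), lexicon_dir = NULL, format = "json",
               fixtures = NULL, output = NULL, log_level = "quiet")
  known <- c("--input", "--lexicon-dir", "--format", "--fixture-annotations",
             "--output", "--log-level")
  i <- 1L
  while (i <= length(argv)) {
    flag <- argv[i]
    if (flag == "--help") {
      message(usage)
      return(0L)
    }
    if (!flag %in% known) {
      message(sprintf("unknown flag: %s", flag))
      message(usage)
      return(2L)
    }
    if (i + 1L > length(argv)) {
      message(sprintf("missing value for %s", flag))
      message(usage)
      return(2L)
    }
    val <- argv[i + 1L]
    switch(flag,
      "--input" = { opts$input <- c(opts$input, val) },
      "--lexicon-dir" = { opts$lexicon_dir <- val },
      "--format" = { opts$format <- val },
      "--fixture-annotations" = { opts$fixtures <- val },
      "--output" = { opts$output <- val },
      "--log-level" = { opts$log_level <- val }
    )
    i <- i + 2L
  }
  if (!opts$format %in% c("json", "tsv", "brat")) {
    message(sprintf("unknown format: %s (expected json, tsv or brat)", opts$format))
    message(usage)
    return(2L)
  }
  if (length(opts$input) == 0) {
    message("at least one --input file is required")
    message(usage)
    return(2L)
  }
  if (!is.null(opts$output) && length(opts$input) > 1) {
    message("--output can only be used with a single --input")
    return(2L)
  }
  missing <- opts$input[!file.exists(opts$input)]
  if (length(missing)) {
    message(sprintf("input file(s) not found: %s", paste(missing, collapse = ", ")))
    return(2L)
  }
  gaz <- tryCatch({
    if (is.null(opts$lexicon_dir)) default_gazetteers()
    else {
      if (!dir.exists(opts$lexicon_dir)) stop(sprintf("lexicon dir not found: %s", opts$lexicon_dir))
      default_gazetteers(opts$lexicon_dir)
    }
  }, error = function(e) e)
  if (inherits(gaz, "error")) {
    message(conditionMessage(gaz))
    return(2L)
  }
  backend <- builtin_annotation_backend()
  if (!is.null(opts$fixtures)) {
    if (!dir.exists(opts$fixtures)) {
      message(sprintf("fixture-annotations dir not found: %s", opts$fixtures))
      return(2L)
    }
    files <- list.files(opts$fixtures, pattern = "\\.tsv$", full.names = TRUE)
    anns <- lapply(files, read_fixture_annotation)
    backend <- fixture_annotation_backend(anns, fallback = builtin_annotation_backend())
  }
  fmt <- c(json = "jsonl", tsv = "tsv", brat = "brat")[[opts$format]]
  ext <- c(json = ".jsonl", tsv = ".tsv", brat = ".ann")[[opts$format]]
  for (f in opts$input) {
    text <- paste(readLines(f, encoding = "UTF-8", warn = FALSE), collapse = "\n")
    ents <- extract_document(text, gazetteers = gaz, backend = backend)
    if (identical(opts$log_level, "info")) {
      message(sprintf("%s: %d sentences, %d entities", f,
                      length(segment_sentences(text)), nrow(ents)))
    }
    dest <- if (!is.null(opts$output)) opts$output else paste0(f, ext)
    write_entities(ents, dest, format = fmt)
  }
  0L
}
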