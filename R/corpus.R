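#' Labeled sentence
#'
#' A sentence is the universal I/O unit: parallel vectors of surface tokens
#' and position tags.  Tags are `"O"` or `"<P>-<Type>"` with `P` drawn from
#' `B,I,E,S` (IOBES) or `B,I` (IOB2).
#'
#' @param tokens character vector of surface tokens (length >= 1).
#' @param labels character vector of tags, same length as `tokens`.
#' @return A `labeled_sentence`: a list with elements `tokens` and `labels`.
#' @export
labeled_sentence <- function(tokens, labels) {
  tokens <- as.character(tokens)
  labels <- as.character(labels)
  if (length(tokens) < 1L)
    stop("a sentence needs at least one token")
  if (length(tokens) != length(labels))
    stop("tokens and labels differ in length (", length(tokens), " vs ",
         length(labels), ")")
  structure(list(tokens = tokens, labels = labels),
            class = "labeled_sentence")
}

#' Labeled corpus
#'
#' A list of [labeled_sentence()] objects together with the ordered label set,
#' the tagging scheme, and a split tag.
#'
#' @param sentences list of `labeled_sentence` objects.
#' @param label_set ordered character vector of the distinct tags; derived
#'   from the sentences when `NULL`.  Always contains `"O"`.
#' @param scheme `"IOBES"` or `"IOB2"`.
#' @param split one of `"train"`, `"dev"`, `"test"`, `"all"`.
#' @return A `ner_corpus` object.
#' @export
ner_corpus <- function(sentences, label_set = NULL,
                       scheme = c("IOBES", "IOB2"), split = "all") {
  scheme <- match.arg(scheme)
  stopifnot(is.list(sentences))
  observed <- sort(unique(unlist(lapply(sentences, `[[`, "labels"))))
  if (is.null(label_set)) label_set <- observed
  label_set <- sort(unique(c("O", label_set)))
  missing <- setdiff(observed, label_set)
  if (length(missing) > 0L)
    stop("labels present in sentences but not in label_set: ",
         paste(missing, collapse = ", "))
  structure(sentences,
            label_set = label_set, scheme = scheme, split = split,
            class = "ner_corpus")
}

#' @export
print.ner_corpus <- function(x, ...) {
  nt <- sum(vapply(x, function(s) length(s$tokens), integer(1)))
  cat(sprintf("<ner_corpus> %d sentences, %d tokens, %d labels (%s, split=%s)\n",
              length(x), nt, length(attr(x, "label_set")),
              attr(x, "scheme"), attr(x, "split")))
  invisible(x)
}

#' @export
`[.ner_corpus` <- function(x, i) {
  ner_corpus(unclass(x)[i], label_set = attr(x, "label_set"),
             scheme = attr(x, "scheme"), split = attr(x, "split"))
}

label_set <- function(corpus) attr(corpus, "label_set")

tagging_scheme <- function(corpus) attr(corpus, "scheme")

#' Read a two-column CoNLL corpus
#'
#' One `token<sep>tag` line per token, blank line between sentences.  Lines
#' starting with `-DOCSTART-` (document markers in some corpus dialects) are
#' skipped.
#'
#' @param path file to read (UTF-8).
#' @param column_separator column separator; the default `"\t"` falls back to
#'   splitting on whitespace runs for lines that contain no tab.
#' @param scheme declared tagging scheme, `"IOBES"` or `"IOB2"`; tag syntax is
#'   validated against it.
#' @param extra_labels tags to add to the label set beyond those observed.
#' @return A [ner_corpus()].
#' @export
read_conll <- function(path, column_separator = "\t",
                       scheme = c("IOBES", "IOB2"), extra_labels = character()) {
  scheme <- match.arg(scheme)
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  if (length(lines) == 0L) stop("empty file: ", path)
  tag_re <- if (scheme == "IOBES") "^(O|[BIES]-.+)$" else "^(O|[BI]-.+)$"
  sentences <- list()
  toks <- character(); tags <- character()
  flush <- function() {
    if (length(toks) > 0L)
      sentences[[length(sentences) + 1L]] <<- labeled_sentence(toks, tags)
    toks <<- character(); tags <<- character()
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (grepl("^\\s*$", line)) { flush(); next }
    if (startsWith(line, "-DOCSTART-")) next
    parts <- strsplit(line, column_separator, fixed = TRUE)[[1]]
    if (length(parts) < 2L && column_separator == "\t")
      parts <- strsplit(trimws(line), "\\s+")[[1]]
    if (length(parts) < 2L)
      stop("malformed line ", ln, " in ", path,
           ": expected >= 2 columns, got ", length(parts))
    tag <- parts[[length(parts)]]
    if (!grepl(tag_re, tag))
      stop("line ", ln, " in ", path, ": tag '", tag,
           "' is not valid ", scheme)
    toks <- c(toks, parts[[1]])
    tags <- c(tags, tag)
  }
  flush()
  if (length(sentences) == 0L) stop("no sentences found in ", path)
  ner_corpus(sentences,
             label_set = sort(unique(c(unlist(lapply(sentences, `[[`, "labels")),
                                       extra_labels, "O"))),
             scheme = scheme)
}

#' Write a corpus in two-column CoNLL format
#'
#' Emits `token<sep>tag` lines with a blank line after every sentence and a
#' terminal newline, so that `read_conll(write_conll(x))` round-trips.
#'
#' @param corpus a [ner_corpus()]; must be non-empty.
#' @param path output file.
#' @param column_separator column separator (default tab).
#' @export
write_conll <- function(corpus, path, column_separator = "\t") {
  if (length(corpus) == 0L) stop("refusing to write an empty corpus")
  blocks <- vapply(corpus, function(s) {
    paste0(paste(s$tokens, s$labels, sep = column_separator, collapse = "\n"),
           "\n")
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(blocks, con, sep = "\n", useBytes = TRUE)
  invisible(NULL)
}
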