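# Tag-scheme utilities: IOB2 <-> IOBES conversion, span extraction with
# conlleval-style repair of invalid sequences, and corpus statistics.

split_tag <- function(tag) {
  # -> c(position, type); "O" -> c("O", "")
  if (tag == "O") return(c("O", ""))
  c(substr(tag, 1L, 1L), substr(tag, 3L, nchar(tag)))
}

#' Check a label sequence against the IOBES automaton
#'
#' Valid IOBES requires I/E to continue a same-type B/I, and every B/I span to
#' be terminated by an E of the same type.
#'
#' @param labels character vector of IOBES tags.
#' @return `TRUE` or `FALSE`.
#' @export
valid_iobes <- function(labels) {
  open <- NULL # type of an open span (after B or I)
  for (tag in labels) {
    pt <- split_tag(tag)
    p <- pt[[1]]; ty <- pt[[2]]
    if (p %in% c("I", "E")) {
      if (is.null(open) || open != ty) return(FALSE)
    } else if (!is.null(open)) {
      return(FALSE) # open span interrupted by O/B/S
    }
    open <- if (p %in% c("B", "I")) ty else NULL
  }
  is.null(open)
}

#' Convert a label sequence between tagging schemes
#'
#' Span content is preserved exactly: IOB2 -> IOBES marks single-token spans
#' `S-` and final tokens of multi-token spans `E-`; IOBES -> IOB2 collapses
#' `S-` to `B-` and `E-` to `I-`.
#'
#' @param labels character vector of tags, valid in `from_scheme`.
#' @param from_scheme,to_scheme `"IOB2"` or `"IOBES"`.
#' @param strict if `TRUE`, an invalid input sequence is an error; if `FALSE`
#'   it is first repaired by the conlleval convention (see
#'   [extract_entity_spans()]).
#' @return character vector of tags in `to_scheme`.
#' @export
convert_tagging_scheme <- function(labels, from_scheme, to_scheme,
                                   strict = TRUE) {
  from_scheme <- match.arg(from_scheme, c("IOB2", "IOBES"))
  to_scheme <- match.arg(to_scheme, c("IOB2", "IOBES"))
  as_iobes <- if (from_scheme == "IOBES") labels else iob2_to_iobes(labels)
  if (strict && !valid_iobes(as_iobes))
    stop("invalid ", from_scheme, " label sequence: ",
         paste(labels, collapse = " "))
  spans <- extract_entity_spans(as_iobes)
  spans_to_labels(spans, length(labels), scheme = to_scheme)
}

iob2_to_iobes <- function(labels) {
  n <- length(labels)
  out <- labels
  for (i in seq_len(n)) {
    pt <- split_tag(labels[[i]])
    if (pt[[1]] == "O") next
    nxt <- if (i < n) split_tag(labels[[i + 1]]) else c("O", "")
    continues <- nxt[[1]] == "I" && nxt[[2]] == pt[[2]]
    if (pt[[1]] == "B" && !continues) {
      out[[i]] <- paste0("S-", pt[[2]])
    } else if (pt[[1]] == "I" && !continues) {
      out[[i]] <- paste0("E-", pt[[2]])
    }
  }
  out
}

#' Extract entity spans from an IOBES label sequence
#'
#' Invalid sequences (which unconstrained decoding can produce) are never
#' rejected; they are repaired by the conlleval convention: an `I-`/`E-`
#' without a compatible open span starts a new span, and a type change inside
#' a span closes the previous span.
#'
#' @param labels character vector of IOBES tags.
#' @return data.frame with columns `start`, `end` (0-based token indices,
#'   inclusive) and `type`, sorted by `start`.
#' @export
extract_entity_spans <- function(labels) {
  starts <- integer(); ends <- integer(); types <- character()
  open_start <- NA_integer_; open_type <- NA_character_
  close_open <- function(end_idx) {
    if (!is.na(open_start)) {
      starts <<- c(starts, open_start); ends <<- c(ends, end_idx)
      types <<- c(types, open_type)
    }
    open_start <<- NA_integer_; open_type <<- NA_character_
  }
  for (i in seq_along(labels)) {
    pt <- split_tag(labels[[i]])
    p <- pt[[1]]; ty <- pt[[2]]
    if (p == "O") {
      close_open(i - 2L)
    } else if (p == "B") {
      close_open(i - 2L)
      open_start <- i - 1L; open_type <- ty
    } else if (p == "S") {
      close_open(i - 2L)
      starts <- c(starts, i - 1L); ends <- c(ends, i - 1L); types <- c(types, ty)
    } else if (p == "I") {
      if (is.na(open_start) || open_type != ty) {
        close_open(i - 2L)                    # repair: I- opens a new span
        open_start <- i - 1L; open_type <- ty
      }
    } else if (p == "E") {
      if (!is.na(open_start) && open_type == ty) {
        close_open(i - 1L)
      } else {
        close_open(i - 2L)                    # repair: bare E- is a singleton
        starts <- c(starts, i - 1L); ends <- c(ends, i - 1L)
        types <- c(types, ty)
      }
    }
  }
  close_open(length(labels) - 1L)             # repair: unterminated span
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}

#' Render entity spans as a label sequence
#'
#' Inverse of [extract_entity_spans()] on valid input.
#'
#' @param spans data.frame with `start`, `end` (0-based, inclusive), `type`;
#'   spans must lie in `[0, n)` and must not overlap.
#' @param n sentence length in tokens.
#' @param scheme output scheme, `"IOBES"` (default) or `"IOB2"`.
#' @return character vector of `n` tags.
#' @export
spans_to_labels <- function(spans, n, scheme = c("IOBES", "IOB2")) {
  scheme <- match.arg(scheme)
  labels <- rep("O", n)
  if (NROW(spans) == 0L) return(labels)
  spans <- spans[order(spans$start), , drop = FALSE]
  if (any(spans$start < 0L) || any(spans$end >= n) ||
      any(spans$start > spans$end))
    stop("span out of range for sentence of length ", n)
  if (any(spans$start[-1L] <= spans$end[-NROW(spans)]))
    stop("overlapping spans")
  for (r in seq_len(NROW(spans))) {
    s <- spans$start[[r]] + 1L; e <- spans$end[[r]] + 1L
    ty <- spans$type[[r]]
    if (scheme == "IOB2") {
      labels[s] <- paste0("B-", ty)
      if (e > s) labels[(s + 1L):e] <- paste0("I-", ty)
    } else if (s == e) {
      labels[s] <- paste0("S-", ty)
    } else {
      labels[s] <- paste0("B-", ty)
      labels[e] <- paste0("E-", ty)
      if (e > s + 1L) labels[(s + 1L):(e - 1L)] <- paste0("I-", ty)
    }
  }
  labels
}

#' Corpus-level entity statistics
#'
#' Sentence count, entity count, and the maximum and average entity length in
#' tokens, computed from the extracted entity spans of every sentence.
#'
#' @param corpus a [ner_corpus()] (IOBES; IOB2 corpora are converted first).
#' @return list with `n_sentences`, `n_entities`, `max_entity_len`,
#'   `avg_entity_len` (rounded to 2 decimals; 0s when there are no entities).
#' @export
corpus_statistics <- function(corpus) {
  lens <- unlist(lapply(corpus, function(s) {
    labs <- s$labels
    if (tagging_scheme(corpus) == "IOB2") labs <- iob2_to_iobes(labs)
    sp <- extract_entity_spans(labs)
    sp$end - sp$start + 1L
  }))
  if (length(lens) == 0L)
    return(list(n_sentences = length(corpus), n_entities = 0L,
                max_entity_len = 0L, avg_entity_len = 0))
  list(n_sentences = length(corpus),
       n_entities = length(lens),
       max_entity_len = max(lens),
       avg_entity_len = round(mean(lens), 2))
}
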