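# Independent reference implementations used as oracles: a predicate-based
# conlleval-style chunker (start-of-chunk / end-of-chunk tests) and a scorer
# built on it.  Deliberately written differently from the package's
# state-machine span extractor.

ref_extract_spans <- function(labels) {
  n <- length(labels)
  pos <- ifelse(labels == "O", "O", substr(labels, 1, 1))
  typ <- ifelse(labels == "O", "", substring(labels, 3))
  starts <- integer(0); ends <- integer(0); types <- character(0)
  open <- NA_integer_
  for (i in seq_len(n)) {
    p <- pos[i]; ty <- typ[i]
    if (p == "O") next
    prev_p <- if (i > 1) pos[i - 1] else "O"
    prev_ty <- if (i > 1) typ[i - 1] else ""
    nxt_p <- if (i < n) pos[i + 1] else "O"
    nxt_ty <- if (i < n) typ[i + 1] else ""
    is_start <- p %in% c("B", "S") ||
      (p %in% c("I", "E") &&
         (prev_p == "O" || prev_ty != ty || prev_p %in% c("E", "S")))
    is_end <- p %in% c("E", "S") ||
      !(nxt_p %in% c("I", "E") && nxt_ty == ty)
    if (is_start) open <- i
    if (is_end && !is.na(open)) {
      starts <- c(starts, open - 1L); ends <- c(ends, i - 1L)
      types <- c(types, ty)
      open <- NA_integer_
    }
  }
  data.frame(start = starts, end = ends, type = types,
             stringsAsFactors = FALSE)
}

ref_entity_f1 <- function(gold, pred) {
  gk <- character(0); pk <- character(0)
  for (i in seq_along(gold)) {
    gs <- ref_extract_spans(gold[[i]]$labels)
    ps <- ref_extract_spans(pred[[i]]$labels)
    if (NROW(gs)) gk <- c(gk, sprintf("%d|%d|%d|%s", i, gs$start, gs$end, gs$type))
    if (NROW(ps)) pk <- c(pk, sprintf("%d|%d|%d|%s", i, ps$start, ps$end, ps$type))
  }
  tp <- sum(pk %in% gk)
  p <- if (length(pk)) 100 * tp / length(pk) else 0
  r <- if (length(gk)) 100 * tp / length(gk) else 0
  f <- if (p + r > 0) 2 * p * r / (p + r) else 0
  list(precision = round(p, 2), recall = round(r, 2), f1 = round(f, 2),
       tp = tp, fp = length(pk) - tp, fn = length(gk) - tp)
}

# a random valid IOBES sequence built from randomly placed spans
random_valid_iobes <- function(n, types = c("X", "Y")) {
  starts <- integer(0); ends <- integer(0); tys <- character(0)
  i <- 1L
  while (i <= n) {
    if (stats::runif(1) < 0.35) {
      len <- sample.int(min(3L, n - i + 1L), 1L)
      starts <- c(starts, i - 1L); ends <- c(ends, i + len - 2L)
      tys <- c(tys, sample(types, 1L))
      i <- i + len
    } else {
      i <- i + 1L
    }
  }
  spans_to_labels(data.frame(start = starts, end = ends, type = tys,
                             stringsAsFactors = FALSE), n)
}

# arbitrary (usually invalid) IOBES tag sequence
random_any_iobes <- function(n, types = c("X", "Y")) {
  tags <- c("O", as.vector(outer(c("B-", "I-", "E-", "S-"), types, paste0)))
  sample(tags, n, replace = TRUE)
}

random_label_corpus <- function(n_sentences, len_range = c(1L, 10L),
                                valid = TRUE, types = c("X", "Y")) {
  sentences <- lapply(seq_len(n_sentences), function(i) {
    n <- sample(len_range[1]:len_range[2], 1L)
    labs <- if (valid) random_valid_iobes(n, types) else random_any_iobes(n, types)
    labeled_sentence(sprintf("t%02d", seq_len(n)), labs)
  })
  all_tags <- sort(unique(c("O", as.vector(outer(c("B-", "I-", "E-", "S-"),
                                                 types, paste0)))))
  ner_corpus(sentences, label_set = all_tags, scheme = "IOBES")
}

# small random chain potentials
random_potentials <- function(n, l, scale = 1) {
  chain_potentials(matrix(stats::rnorm(n * l, sd = scale), n, l),
                   array(stats::rnorm(max(n - 1, 0) * l * l, sd = scale),
                         dim = c(max(n - 1, 0), l, l)))
}
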