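# Entity-level exact-match scoring with CoNLL semantics: a predicted span
# counts only if sentence, start, end and type all equal a gold span.
# Micro-averaged over all spans; percentages to 2 decimals.

#' Entity-level exact-match precision / recall / F1
#'
#' Extracts entity spans from the gold and predicted label sequences
#' (predicted sequences may be invalid IOBES from unconstrained decoding and
#' are repaired by the conlleval convention, see [extract_entity_spans()])
#' and counts exact matches on (sentence, start, end, type).
#'
#' @param gold,pred [ner_corpus()] objects with identical sentence count and
#'   per-sentence lengths.
#' @return list with `tp`, `fp`, `fn`, `precision`, `recall`, `f1`
#'   (percentages, 0-100) and `by_type` (a data.frame with the same columns
#'   per entity type).
#' @export
entity_f1 <- function(gold, pred) {
  if (length(gold) != length(pred))
    stop("gold and pred differ in sentence count")
  span_keys <- function(corpus) {
    unlist(lapply(seq_along(corpus), function(i) {
      s <- corpus[[i]]
      sp <- extract_entity_spans(s$labels)
      if (NROW(sp) == 0L) return(character())
      paste(i, sp$start, sp$end, sp$type, sep = ":")
    }))
  }
  for (i in seq_along(gold))
    if (length(gold[[i]]$tokens) != length(pred[[i]]$tokens))
      stop("sentence ", i, " length mismatch between gold and pred")
  g <- span_keys(gold)
  p <- span_keys(pred)
  tally <- function(g, p) {
    tp <- length(intersect(g, p))
    fp <- length(p) - tp
    fn <- length(g) - tp
    precision <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
    recall <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
    f1 <- if (precision + recall > 0)
      2 * precision * recall / (precision + recall) else 0
    list(tp = tp, fp = fp, fn = fn,
         precision = round(precision, 2), recall = round(recall, 2),
         f1 = round(f1, 2))
  }
  overall <- tally(g, p)
  types <- sort(unique(sub("^.*:", "", c(g, p))))
  by_type <- do.call(rbind, lapply(types, function(ty) {
    sel <- function(keys) keys[endsWith(keys, paste0(":", ty))]
    data.frame(type = ty, as.data.frame(tally(sel(g), sel(p))),
               stringsAsFactors = FALSE)
  }))
  overall$by_type <- by_type
  overall
}

#' Train and evaluate with repeated random initializations
#'
#' Repeats the full train-and-test protocol `k` times with distinct seeds
#' and reports the arithmetic mean of the entity-level scores alongside the
#' per-run results.
#'
#' @param corpus,dev_corpus,test_corpus train / dev / test splits (IOBES).
#' @param config a [train_config()]; its seed is replaced per run.
#' @param seeds integer seeds, one per repeat (default 5 repeats).
#' @param mode decoding mode passed to [predict_corpus()].
#' @param embeddings as in [train()].
#' @param verbose print per-run progress.
#' @return list with `mean` (precision/recall/f1 averaged over runs) and
#'   `runs` (list of per-run [entity_f1()] results, with the trained models'
#'   training logs attached as `"log"` attributes).
#' @export
repeated_runs <- function(corpus, dev_corpus, test_corpus, config,
                          seeds = 1:5, mode = "combined", embeddings = NULL,
                          verbose = FALSE) {
  if (anyDuplicated(seeds)) stop("seeds must be distinct")
  runs <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    model <- train(corpus, dev_corpus, cfg, embeddings = embeddings,
                   verbose = verbose)
    res <- entity_f1(test_corpus,
                     predict_corpus(model, test_corpus, mode = mode))
    attr(res, "log") <- model$log
    res
  })
  list(mean = list(
    precision = round(mean(vapply(runs, `[[`, numeric(1), "precision")), 2),
    recall = round(mean(vapply(runs, `[[`, numeric(1), "recall")), 2),
    f1 = round(mean(vapply(runs, `[[`, numeric(1), "f1")), 2)),
    runs = runs)
}
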