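# Synthetic corpus generator.  The corpora emulate the one statistical
# property the dynamic-transition model targets: multi-token entities whose
# segmentation around a conjunction depends on nearby context.  Two
# same-type entities joined by a conjunction token are labeled as ONE entity
# if and only if a trigger token occurs within a fixed window before the
# construct; otherwise they are two entities and the conjunction is O.  The
# label transition at the conjunction is therefore decidable only from
# context, never from the label pair's identity alone.

#' Synthetic-generator configuration
#'
#' Token surfaces are synthetic symbols; vocabularies are disjoint by role
#' (generic, per-type entity cores, modifiers, triggers, conjunctions).
#'
#' @param seed RNG seed; generation is fully deterministic given the seed.
#' @param n_sentences number of sentences to generate.
#' @param length_mean,length_sd,length_range sentence length draw: rounded
#'   Normal(mean, sd) clipped to the range.
#' @param n_generic,n_core,n_modifier,n_trigger vocabulary sizes (cores are
#'   per entity type).
#' @param entity_types entity type names.
#' @param p_entity_start probability of starting an entity construct at an
#'   eligible position.
#' @param modifier_counts,core_counts supports of the uniform draws for
#'   modifier and core token counts per entity.
#' @param p_conj probability that a construct joins two entities with a
#'   conjunction.
#' @param p_trigger probability that a conjunction construct is preceded by
#'   a trigger (and hence labeled as one joined entity).
#' @param conjunctions conjunction token surfaces.
#' @param trigger_window maximum distance (tokens) from trigger to construct.
#' @return a `generator_config` list.
#' @export
generator_config <- function(seed = 1L, n_sentences = 1000L,
                             length_mean = 18, length_sd = 5,
                             length_range = c(8L, 40L),
                             n_generic = 500L, n_core = 60L,
                             n_modifier = 30L, n_trigger = 10L,
                             entity_types = c("TypeA", "TypeB"),
                             p_entity_start = 0.12,
                             modifier_counts = 0:2, core_counts = 1:3,
                             p_conj = 0.3, p_trigger = 0.5,
                             conjunctions = c("and", "/", "or"),
                             trigger_window = 3L) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_sentences >= 1L, cfg$p_entity_start >= 0,
            cfg$p_entity_start <= 1, cfg$p_conj >= 0, cfg$p_conj <= 1,
            cfg$p_trigger >= 0, cfg$p_trigger <= 1,
            length(cfg$entity_types) >= 1L, cfg$trigger_window >= 1L)
  class(cfg) <- "generator_config"
  cfg
}

generator_vocab <- function(cfg) {
  list(generic = sprintf("w%04d", seq_len(cfg$n_generic)),
       cores = stats::setNames(lapply(cfg$entity_types, function(ty) {
         sprintf("core%s%02d", sub("^Type", "", ty), seq_len(cfg$n_core))
       }), cfg$entity_types),
       modifier = sprintf("mod%02d", seq_len(cfg$n_modifier)),
       trigger = sprintf("trig%02d", seq_len(cfg$n_trigger)))
}

#' Generate a synthetic labeled corpus
#'
#' See [generator_config()] for the sentence model.  Every emitted label
#' sequence is valid IOBES by construction.  Realized construct counts are
#' attached as the `"generator_stats"` attribute.
#'
#' @param config a [generator_config()].
#' @return a [ner_corpus()] in IOBES with the full 4-per-type + O label set.
#' @export
generate_corpus <- function(config) {
  if (!inherits(config, "generator_config")) stop("invalid generator config")
  set.seed(config$seed)
  voc <- generator_vocab(config)
  pick <- function(x, n = 1L) x[sample.int(length(x), n, replace = TRUE)]
  n_joined <- 0L; n_split <- 0L; n_conj_sent <- 0L
  sentences <- vector("list", config$n_sentences)
  for (si in seq_len(config$n_sentences)) {
    len <- round(stats::rnorm(1, config$length_mean, config$length_sd))
    len <- min(max(len, config$length_range[[1]]), config$length_range[[2]])
    tokens <- character(0)
    spans <- list()
    has_conj <- FALSE
    entity_tokens <- function(ty) {
      c(pick(voc$modifier, pick(config$modifier_counts)),
        pick(voc$cores[[ty]], pick(config$core_counts)))
    }
    while (length(tokens) < len) {
      construct <- NULL
      if (stats::runif(1) < config$p_entity_start) {
        ty <- pick(config$entity_types)
        e1 <- entity_tokens(ty)
        if (stats::runif(1) < config$p_conj) {
          e2 <- entity_tokens(ty)
          conj <- pick(config$conjunctions)
          if (stats::runif(1) < config$p_trigger) {
            # trigger -> the joined construct is ONE entity (conjunction I-)
            gap <- pick(0:(config$trigger_window - 1L))
            pre <- c(pick(voc$trigger), pick(voc$generic, gap)[seq_len(gap)])
            body <- c(e1, conj, e2)
            construct <- list(tokens = c(pre, body),
                              spans = list(list(offset = length(pre),
                                                len = length(body), type = ty)),
                              joined = TRUE)
          } else {
            # no trigger nearby -> TWO entities, conjunction labeled O;
            # pad so the preceding window is trigger-free
            tail_win <- utils::tail(tokens, config$trigger_window)
            pad <- 0L
            while (any(startsWith(utils::tail(c(tail_win,
                                                rep("w", pad)), # pad symbols
                                              config$trigger_window), "trig")))
              pad <- pad + 1L
            pre <- pick(voc$generic, pad)[seq_len(pad)]
            construct <- list(tokens = c(pre, e1, conj, e2),
                              spans = list(
                                list(offset = length(pre), len = length(e1),
                                     type = ty),
                                list(offset = length(pre) + length(e1) + 1L,
                                     len = length(e2), type = ty)),
                              joined = FALSE)
          }
          has_conj_here <- TRUE
        } else {
          construct <- list(tokens = e1,
                            spans = list(list(offset = 0L, len = length(e1),
                                              type = ty)),
                            joined = NA)
          has_conj_here <- FALSE
        }
        if (length(tokens) + length(construct$tokens) > len) {
          construct <- NULL # not enough room; fall through to a generic token
        } else if (has_conj_here) {
          has_conj <- TRUE
          if (isTRUE(construct$joined)) n_joined <- n_joined + 1L
          else n_split <- n_split + 1L
        }
      }
      if (is.null(construct)) {
        tokens <- c(tokens, pick(voc$generic))
      } else {
        base <- length(tokens)
        for (sp in construct$spans)
          spans[[length(spans) + 1L]] <-
            data.frame(start = base + sp$offset,
                       end = base + sp$offset + sp$len - 1L,
                       type = sp$type, stringsAsFactors = FALSE)
        tokens <- c(tokens, construct$tokens)
      }
    }
    if (has_conj) n_conj_sent <- n_conj_sent + 1L
    span_df <- if (length(spans) > 0L) do.call(rbind, spans)
    else data.frame(start = integer(), end = integer(), type = character())
    sentences[[si]] <- labeled_sentence(
      tokens, spans_to_labels(span_df, length(tokens), scheme = "IOBES"))
  }
  full_labels <- sort(c("O", as.vector(outer(c("B-", "I-", "E-", "S-"),
                                             config$entity_types, paste0))))
  corpus <- ner_corpus(sentences, label_set = full_labels, scheme = "IOBES")
  attr(corpus, "generator_stats") <-
    list(n_joined = n_joined, n_split = n_split,
         n_conj_sentences = n_conj_sent,
         frac_conj_sentences = n_conj_sent / config$n_sentences)
  corpus
}

#' Split a corpus into train / dev / test
#'
#' Seeded shuffle split; the three parts are disjoint and exhaustive.
#'
#' @param corpus a [ner_corpus()].
#' @param fractions length-3 numeric, positive, summing to 1.
#' @param seed shuffle seed.
#' @return named list of corpora `train`, `dev`, `test` with the split
#'   attribute set accordingly.
#' @export
make_split <- function(corpus, fractions = c(0.8, 0.1, 0.1), seed = 1L) {
  if (length(fractions) != 3L || any(fractions <= 0))
    stop("fractions must be 3 positive numbers")
  if (abs(sum(fractions) - 1) > 1e-8) stop("fractions must sum to 1")
  set.seed(seed)
  n <- length(corpus)
  ord <- sample.int(n)
  n_train <- round(n * fractions[[1]])
  n_dev <- round(n * fractions[[2]])
  take <- function(idx, split) {
    sub <- corpus[ord[idx]]
    attr(sub, "split") <- split
    sub
  }
  list(train = take(seq_len(n_train), "train"),
       dev = take(n_train + seq_len(n_dev), "dev"),
       test = take(seq((n_train + n_dev + 1L), n), "test"))
}
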