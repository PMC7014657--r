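# The training study shared by the trainability and ablation acceptance
# checks: one corpus (5,000 sentences, generator seed 1, generator defaults),
# an 80/10/10 split, and five training runs (seeds 1..5) of 25 epochs with
# the standard regimen at model sizes d = 64, c = 32, m = 16.  Each trained
# joint model is decoded in all four modes on the test split.  Cached so the
# study runs once per test session.

.study_cache <- new.env(parent = emptyenv())

training_study <- function(seeds = 1:5) {
  key <- paste(seeds, collapse = ",")
  if (!is.null(.study_cache[[key]])) return(.study_cache[[key]])
  corpus <- generate_corpus(generator_config(seed = 1, n_sentences = 5000))
  splits <- make_split(corpus, c(0.8, 0.1, 0.1), seed = 1)
  res <- do.call(rbind, lapply(seeds, function(s) {
    cfg <- train_config(d = 64, c = 32, m = 16, max_epochs = 25L,
                        seed = as.integer(s))
    model <- train(splits$train, splits$dev, cfg)
    vapply(c("combined", "unary", "pairwise", "ensemble"), function(mode)
      entity_f1(splits$test, predict_corpus(model, splits$test, mode))$f1,
      numeric(1))
  }))
  rownames(res) <- paste0("seed", seeds)
  .study_cache[[key]] <- res
  res
}
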