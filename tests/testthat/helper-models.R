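# Small model fixtures shared across test files.

tiny_generator <- function(seed = 5, n = 12) {
  generator_config(seed = seed, n_sentences = n, length_mean = 8,
                   length_range = c(5L, 12L), n_generic = 30, n_core = 5,
                   n_modifier = 4, n_trigger = 2)
}

tiny_model <- function(seed = 2, n = 8, d = 8, c = 4, m = 4, ...) {
  corp <- generate_corpus(tiny_generator(seed = seed + 100, n = n))
  cfg <- train_config(d = d, c = c, m = m, seed = seed, trainable_dim = 6, ...)
  list(corpus = corp, config = cfg, model = dyntrans:::new_model(corp, cfg))
}
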