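test_that("generation is deterministic and emits valid IOBES", {
  cfg <- generator_config(seed = 77, n_sentences = 150)
  a <- generate_corpus(cfg)
  b <- generate_corpus(cfg)
  expect_identical(unclass(a), unclass(b))
  expect_true(all(vapply(a, function(s) valid_iobes(s$labels), logical(1))))
  lens <- vapply(a, function(s) length(s$tokens), integer(1))
  expect_true(all(lens >= 8 & lens <= 40))
  expect_length(attr(a, "label_set"), 9L)  # 4 positions x 2 types + O
})

test_that("the conjunction label is decidable only from the trigger context", {
  corp <- generate_corpus(generator_config(seed = 3, n_sentences = 400))
  conj_tokens <- c("and", "/", "or")
  joined <- 0L; split <- 0L
  for (s in corp) {
    spans <- extract_entity_spans(s$labels)
    is_conj <- s$tokens %in% conj_tokens
    for (i in which(is_conj)) {
      lab <- s$labels[[i]]
      trig_before <- function(start0) {
        win <- max(1L, start0 - 2L):max(1L, start0)
        any(startsWith(s$tokens[win[win >= 1 & win <= start0]], "trig"))
      }
      if (lab == "O") {
        split <- split + 1L
        # split reading: entity ends at i-1, next begins at i+1, and no
        # trigger appears in the window before the first entity
        prev_span <- spans[spans$end == i - 2L, ]
        expect_equal(NROW(prev_span), 1L)
        expect_false(trig_before(prev_span$start[[1]]))
      } else {
        joined <- joined + 1L
        # joined reading: the conjunction is inside one span whose start is
        # preceded by a trigger within the window
        inside <- spans[spans$start <= i - 1L & spans$end >= i - 1L, ]
        expect_equal(NROW(inside), 1L)
        expect_true(grepl("^I-", lab))
        expect_true(trig_before(inside$start[[1]]))
      }
    }
  }
  # both continuations of the same surface construct occur
  expect_gt(joined, 20L)
  expect_gt(split, 20L)
  st <- attr(corp, "generator_stats")
  expect_equal(st$n_joined, joined)
  expect_equal(st$n_split, split)
  # trigger share of conjunction constructs near its configured probability
  expect_lt(abs(joined / (joined + split) - 0.5), 0.08)
})

test_that("conjunction frequency matches the generator's own combinatorics", {
  cfg <- generator_config(seed = 1, n_sentences = 5000)
  corp <- generate_corpus(cfg)
  frac <- attr(corp, "generator_stats")$frac_conj_sentences
  # independent Monte-Carlo of the construct process (no token surfaces):
  # walk positions, start a construct w.p. p_entity_start when it fits,
  # make it a conjunction construct w.p. p_conj
  set.seed(4242)
  sim <- replicate(4000, {
    len <- round(stats::rnorm(1, cfg$length_mean, cfg$length_sd))
    len <- min(max(len, cfg$length_range[[1]]), cfg$length_range[[2]])
    emitted <- 0L; any_conj <- FALSE
    while (emitted < len) {
      if (stats::runif(1) < cfg$p_entity_start) {
        conj <- stats::runif(1) < cfg$p_conj
        e1 <- sample(cfg$modifier_counts, 1) + sample(cfg$core_counts, 1)
        csize <- if (!conj) e1 else {
          e2 <- sample(cfg$modifier_counts, 1) + sample(cfg$core_counts, 1)
          trig <- stats::runif(1) < cfg$p_trigger
          e1 + 1L + e2 + if (trig) 1L + sample(0:2, 1) else 0L
        }
        if (emitted + csize <= len) {
          emitted <- emitted + csize
          if (conj) any_conj <- TRUE
        } else emitted <- emitted + 1L
      } else emitted <- emitted + 1L
    }
    any_conj
  })
  expect_equal(frac, mean(sim), tolerance = 0.03)
})

test_that("entity lengths follow the modifier + core convolution", {
  corp <- generate_corpus(generator_config(seed = 6, n_sentences = 1500))
  conj_tokens <- c("and", "/", "or")
  lens <- unlist(lapply(corp, function(s) {
    sp <- extract_entity_spans(s$labels)
    if (NROW(sp) == 0L) return(integer())
    # restrict to simple entities (no conjunction inside the span)
    keep <- vapply(seq_len(NROW(sp)), function(r)
      !any(s$tokens[(sp$start[r] + 1L):(sp$end[r] + 1L)] %in% conj_tokens),
      logical(1))
    sp$end[keep] - sp$start[keep] + 1L
  }))
  emp <- tabulate(lens, 5) / length(lens)
  expected <- c(1, 2, 3, 2, 1) / 9           # U{0,1,2} + U{1,2,3}
  # end-of-sentence room checks slightly favor short entities, so the
  # comparison is on absolute probability mass
  expect_lt(max(abs(emp - expected)), 0.03)
  expect_true(all(lens >= 1 & lens <= 5))
})

test_that("splits are seeded, disjoint, and exhaustive", {
  corp <- generate_corpus(generator_config(seed = 2, n_sentences = 1000))
  sp <- make_split(corp, c(0.8, 0.1, 0.1), seed = 5)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 800L, dev = 100L, test = 100L))
  key <- function(cc) vapply(cc, function(s) paste(s$tokens, collapse = " "),
                             character(1))
  all_keys <- c(key(sp$train), key(sp$dev), key(sp$test))
  expect_setequal(all_keys, key(corp))
  expect_equal(length(all_keys), length(corp))
  sp2 <- make_split(corp, c(0.8, 0.1, 0.1), seed = 5)
  expect_identical(unclass(sp$dev), unclass(sp2$dev))
  expect_error(make_split(corp, c(0.5, 0.5, 0)), "positive")
  expect_error(make_split(corp, c(0.5, 0.3, 0.3)), "sum to 1")
})
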