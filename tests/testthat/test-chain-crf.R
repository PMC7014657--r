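test_that("sequence scores sum the selected node and edge potentials", {
  pot <- chain_potentials(matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE))
  expect_equal(sequence_score(pot, c(1, 2)), 2)
  expect_equal(sequence_score(random_potentials(4, 3, 0), c(1, 2, 3, 1)), 0)
  expect_error(sequence_score(pot, c(1, 5)), "out of range")
  set.seed(21)
  for (i in 1:50) {
    n <- sample(1:6, 1); l <- sample(2:4, 1)
    pot <- random_potentials(n, l)
    y <- sample(l, n, replace = TRUE)
    manual <- sum(vapply(seq_len(n), function(i) pot$nodes[i, y[i]],
                         numeric(1))) +
      if (n > 1) sum(vapply(seq_len(n - 1), function(i)
        pot$edges[i, y[i], y[i + 1]], numeric(1))) else 0
    expect_equal(sequence_score(pot, y), manual)
  }
})

test_that("log-partition matches closed forms and is shift-invariant", {
  expect_equal(log_partition(random_potentials(3, 2, 0)), 3 * log(2))
  expect_equal(log_partition(chain_potentials(matrix(0, 1, 4))), log(4))
  set.seed(2)
  pot <- random_potentials(4, 3)
  base <- log_partition(pot)
  shifted <- pot
  shifted$nodes[2, ] <- shifted$nodes[2, ] + 7.5
  expect_equal(log_partition(shifted), base + 7.5, tolerance = 1e-9)
  expect_equal(viterbi_decode(shifted)$labels, viterbi_decode(pot)$labels)
  # stable for potentials up to +-1e4
  big <- chain_potentials(matrix(c(1e4, -1e4), 1, 2))
  expect_equal(log_partition(big), 1e4, tolerance = 1e-6)
})

test_that("log-likelihoods are normalized log-probabilities", {
  pot <- random_potentials(3, 3, 0)
  for (y in list(c(1, 1, 1), c(3, 2, 1)))
    expect_equal(log_likelihood(pot, y), -3 * log(3))
  set.seed(5)
  pot <- random_potentials(3, 2)
  bf <- brute_force_enumerate(pot)
  expect_equal(sum(bf$probabilities), 1, tolerance = 1e-9)
  # a dominant node score drives the likelihood of its sequence to ~1
  dom <- chain_potentials(matrix(c(50, 0, 50, 0), 2, 2, byrow = TRUE))
  expect_equal(log_likelihood(dom, c(1, 1)), 0, tolerance = 1e-6)
})

test_that("unary potentials broadcast the static transition matrix", {
  A <- matrix(c(0, 1, 2, 3), 2, 2, byrow = TRUE)
  U <- matrix(stats::rnorm(6), 3, 2)
  pot <- unary_potentials(U, A)
  expect_equal(pot$edges[1, , ], A)
  expect_equal(pot$edges[2, , ], A)
  expect_equal(dim(unary_potentials(matrix(0, 1, 2), A)$edges), c(0L, 2L, 2L))
  # direct evaluation of the unary CRF log-likelihood
  y <- c(2, 1, 2)
  direct <- sum(U[cbind(1:3, y)]) + A[y[1], y[2]] + A[y[2], y[3]] -
    brute_force_enumerate(pot)$logZ
  expect_equal(log_likelihood(pot, y), direct, tolerance = 1e-9)
})

test_that("the edges-only pairwise CRF is uniform for single tokens", {
  p1 <- pairwise_potentials(array(0, dim = c(0, 5, 5)), n_pos = 1)
  expect_equal(log_partition(p1), log(5))
  for (y in 1:5) expect_equal(log_likelihood(p1, y), -log(5))
  pz <- pairwise_potentials(array(0, dim = c(2, 3, 3)))
  expect_equal(log_partition(pz), 3 * log(3))
})

test_that("the combined model adds potentials and multiplies distributions", {
  set.seed(11)
  for (i in 1:100) {
    n <- sample(2:5, 1); l <- sample(2:3, 1)
    U <- matrix(stats::rnorm(n * l), n, l)
    A <- matrix(stats::rnorm(l * l), l, l)
    V <- array(stats::rnorm((n - 1) * l * l), dim = c(n - 1, l, l))
    comb <- combine_models(U, V, A)
    y <- sample(l, n, replace = TRUE)
    expect_equal(sequence_score(comb, y),
                 sequence_score(unary_potentials(U, A), y) +
                   sequence_score(pairwise_potentials(V), y),
                 tolerance = 1e-10)
  }
  # V = 0 reduces combined decoding to the unary model
  U <- matrix(stats::rnorm(8), 4, 2); A <- matrix(stats::rnorm(4), 2, 2)
  V0 <- array(0, dim = c(3, 2, 2))
  expect_equal(viterbi_decode(combine_models(U, V0, A))$labels,
               viterbi_decode(unary_potentials(U, A))$labels)
  # combined distribution is the renormalized product of the two models
  set.seed(12)
  for (i in 1:20) {
    n <- sample(2:4, 1); l <- 2
    U <- matrix(stats::rnorm(n * l), n, l)
    A <- matrix(stats::rnorm(l * l), l, l)
    V <- array(stats::rnorm((n - 1) * l * l), dim = c(n - 1, l, l))
    pu <- unary_potentials(U, A); pp <- pairwise_potentials(V)
    bu <- brute_force_enumerate(pu); bp <- brute_force_enumerate(pp)
    prod_unnorm <- bu$probabilities * bp$probabilities
    expect_equal(brute_force_enumerate(combine_models(U, V, A))$probabilities,
                 prod_unnorm / sum(prod_unnorm), tolerance = 1e-9)
  }
})

test_that("Viterbi decoding returns the argmax with lowest-index tie-break", {
  nodes <- matrix(c(0, 3, 5, 1, 2, 9), 3, 2, byrow = TRUE)
  d <- viterbi_decode(chain_potentials(nodes))
  expect_equal(d$labels, c(2, 1, 2))
  expect_equal(d$score, 3 + 5 + 9)
  expect_equal(viterbi_decode(random_potentials(4, 3, 0))$labels,
               rep(1, 4))
})

test_that("the enumeration oracle is exhaustive and refuses huge instances", {
  bf <- brute_force_enumerate(random_potentials(3, 2, 0))
  expect_length(bf$probabilities, 8L)
  expect_equal(sum(bf$probabilities), 1, tolerance = 1e-12)
  expect_error(brute_force_enumerate(random_potentials(20, 5)), "too large")
})

test_that("compiled decoding and partition agree with the R implementation", {
  set.seed(31)
  for (i in 1:60) {
    n <- sample(1:6, 1); l <- sample(2:4, 1)
    pot <- random_potentials(n, l)
    nodes <- t(pot$nodes)
    edges <- if (n > 1) aperm(pot$edges, c(2, 3, 1)) else
      array(0, dim = c(l, l, 0))
    expect_equal(dyntrans:::cpp_log_partition(nodes, edges),
                 log_partition(pot), tolerance = 1e-10)
    cv <- dyntrans:::cpp_viterbi(nodes, edges)
    rv <- viterbi_decode(pot)
    expect_equal(cv$labels, rv$labels)
    expect_equal(cv$score, rv$score, tolerance = 1e-10)
  }
})

test_that("ensemble decoding votes by model-specific log-probability", {
  l <- 2; n <- 3
  # unary strongly prefers (1,1,1); pairwise weakly prefers (2,2,2)
  U <- matrix(c(5, 0, 5, 0, 5, 0), n, l, byrow = TRUE)
  A <- matrix(0, l, l)
  V <- array(0, dim = c(n - 1, l, l))
  V[, 2, 2] <- 0.1
  d <- ensemble_decode(U, A, V)
  expect_equal(d$labels, c(1, 1, 1))
  expect_equal(d$source, "unary")
  # both models agreeing return the shared sequence
  V2 <- array(0, dim = c(n - 1, l, l)); V2[, 1, 1] <- 3
  expect_equal(ensemble_decode(U, A, V2)$labels, c(1, 1, 1))
  # on enumerable instances the winner is the higher-scoring per-model argmax
  set.seed(41)
  for (i in 1:30) {
    U <- matrix(stats::rnorm(n * l), n, l)
    A <- matrix(stats::rnorm(l * l), l, l)
    V <- array(stats::rnorm((n - 1) * l * l), dim = c(n - 1, l, l))
    d <- ensemble_decode(U, A, V)
    pu <- unary_potentials(U, A); pp <- pairwise_potentials(V)
    lu <- log_likelihood(pu, viterbi_decode(pu)$labels)
    lp <- log_likelihood(pp, viterbi_decode(pp)$labels)
    want <- if (lu >= lp) viterbi_decode(pu)$labels else
      viterbi_decode(pp)$labels
    expect_equal(d$labels, want)
  }
})
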