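# Linear-chain CRF inference over generic chain potentials.
#
# A chain over N positions and L labels is scored by node potentials
# (an N x L matrix) and edge potentials (an (N-1) x L x L array whose slice i
# connects positions i and i+1, rows indexed by the PREVIOUS label).  The
# unnormalized score of a label sequence y is
#
#   sum_i nodes[i, y_i] + sum_i edges[i, y_i, y_{i+1}]
#
# and P(y) = exp(score(y) - logZ) with logZ computed by the forward
# algorithm in log space.  Three instantiations are used throughout:
# nodes = U with edges = A broadcast (the unary CRF with its static
# transition matrix), nodes = 0 with edges = V (the pairwise, edges-only
# CRF), and nodes = U with edges = V + A (the combined product of models).

#' Chain potentials
#'
#' @param nodes N x L matrix of node potentials (one row per position).
#' @param edges (N-1) x L x L array; `edges[i, j, k]` scores label `j` at
#'   position `i` followed by label `k` at position `i + 1`.  For `N = 1` use
#'   an empty array (dims `c(0, L, L)`).
#' @return A `chain_potentials` object.
#' @export
chain_potentials <- function(nodes, edges = NULL) {
  nodes <- as.matrix(nodes)
  n <- nrow(nodes); l <- ncol(nodes)
  if (is.null(edges)) edges <- array(0, dim = c(max(n - 1L, 0L), l, l))
  if (length(dim(edges)) != 3L)
    stop("edges must be an (N-1) x L x L array")
  if (!all(dim(edges) == c(max(n - 1L, 0L), l, l)))
    stop("edge dimensions ", paste(dim(edges), collapse = "x"),
         " inconsistent with ", n, " positions and ", l, " labels")
  if (!all(is.finite(nodes)) || !all(is.finite(edges)))
    stop("potentials must be finite")
  structure(list(nodes = nodes, edges = edges), class = "chain_potentials")
}

n_positions <- function(p) nrow(p$nodes)
n_labels <- function(p) ncol(p$nodes)

check_sequence <- function(p, y) {
  if (length(y) != n_positions(p))
    stop("label sequence length ", length(y), " != ", n_positions(p))
  if (any(y < 1L) || any(y > n_labels(p)))
    stop("label index out of range [1, ", n_labels(p), "]")
  as.integer(y)
}

#' Unnormalized score of a label sequence
#'
#' @param potentials a [chain_potentials()].
#' @param y integer label sequence (1-based indices, length N).
#' @return scalar score.
#' @export
sequence_score <- function(potentials, y) {
  y <- check_sequence(potentials, y)
  n <- n_positions(potentials)
  s <- sum(potentials$nodes[cbind(seq_len(n), y)])
  if (n > 1L)
    s <- s + sum(potentials$edges[cbind(seq_len(n - 1L), y[-n], y[-1L])])
  s
}

log_sum_exp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Log-partition function via the forward algorithm
#'
#' `log sum_y exp(score(y))`, computed with a log-space forward recursion
#' (log-sum-exp at every step), numerically stable for large potentials.
#'
#' @inheritParams sequence_score
#' @return scalar `log Z`.
#' @export
log_partition <- function(potentials) {
  n <- n_positions(potentials); l <- n_labels(potentials)
  alpha <- potentials$nodes[1L, ]
  if (n > 1L) {
    for (i in 2L:n) {
      trans <- potentials$edges[i - 1L, , ] # L x L, rows = previous label
      alpha <- potentials$nodes[i, ] +
        apply(alpha + trans, 2L, log_sum_exp)
    }
  }
  log_sum_exp(alpha)
}

#' Log-likelihood of a label sequence
#'
#' `score(y) - logZ`; always `<= 0`.
#'
#' @inheritParams sequence_score
#' @return scalar log-probability.
#' @export
log_likelihood <- function(potentials, y) {
  sequence_score(potentials, y) - log_partition(potentials)
}

#' Chain potentials of the unary CRF
#'
#' Node potentials are the per-token label scores `U`; every edge slice is the
#' static transition matrix `A` (position-independent broadcast).
#'
#' @param U N x L matrix of unary scores.
#' @param A L x L static transition matrix; `A[j, k]` scores the transition
#'   from label `j` to label `k`.
#' @return A [chain_potentials()].
#' @export
unary_potentials <- function(U, A) {
  U <- as.matrix(U); A <- as.matrix(A)
  n <- nrow(U); l <- ncol(U)
  if (!all(dim(A) == c(l, l))) stop("A must be L x L")
  edges <- array(0, dim = c(max(n - 1L, 0L), l, l))
  if (n > 1L) for (i in seq_len(n - 1L)) edges[i, , ] <- A
  chain_potentials(U, edges)
}

#' Chain potentials of the pairwise (edges-only) CRF
#'
#' Node potentials are zero; all structure lives in the context-dependent
#' edge scores `V`.  A single-token sentence therefore has the uniform
#' distribution over the `L` labels.
#'
#' @param V (N-1) x L x L array of dynamic transition scores.
#' @param n_pos number of positions `N`; needed only when `N = 1` (empty `V`).
#' @return A [chain_potentials()].
#' @export
pairwise_potentials <- function(V, n_pos = dim(V)[1] + 1L) {
  l <- dim(V)[2]
  chain_potentials(matrix(0, n_pos, l), V)
}

#' Combined product-of-models potentials
#'
#' Summing the two models' potentials multiplies their unnormalized
#' distributions: nodes are `U`, each edge slice is `V[i] + A`.
#'
#' @inheritParams unary_potentials
#' @inheritParams pairwise_potentials
#' @return A [chain_potentials()].
#' @export
combine_models <- function(U, V, A) {
  U <- as.matrix(U); A <- as.matrix(A)
  n <- nrow(U); l <- ncol(U)
  if (!all(dim(A) == c(l, l))) stop("A must be L x L")
  if (!all(dim(V) == c(max(n - 1L, 0L), l, l)))
    stop("V dimensions inconsistent with U")
  edges <- V
  if (n > 1L) for (i in seq_len(n - 1L)) edges[i, , ] <- V[i, , ] + A
  chain_potentials(U, edges)
}

#' Viterbi decoding
#'
#' Returns the highest-scoring label sequence.  Ties are broken toward the
#' lowest label index at every backtracking step, making the decode
#' deterministic.
#'
#' @inheritParams sequence_score
#' @return list with `labels` (integer sequence) and `score`.
#' @export
viterbi_decode <- function(potentials) {
  n <- n_positions(potentials); l <- n_labels(potentials)
  delta <- potentials$nodes[1L, ]
  back <- matrix(1L, n, l)
  if (n > 1L) {
    for (i in 2L:n) {
      trans <- potentials$edges[i - 1L, , ]
      cand <- delta + trans                 # L x L: rows previous, cols current
      best_prev <- apply(cand, 2L, which.max) # which.max takes lowest on ties
      back[i, ] <- best_prev
      delta <- potentials$nodes[i, ] + cand[cbind(best_prev, seq_len(l))]
    }
  }
  y <- integer(n)
  y[n] <- which.max(delta)
  if (n > 1L) for (i in n:2L) y[i - 1L] <- back[i, y[i]]
  list(labels = y, score = unname(delta[y[n]]))
}

#' Ensemble decoding by per-model vote
#'
#' Decodes the unary CRF and the pairwise CRF separately and returns the
#' candidate whose own model assigns it the higher log-probability
#' (score minus that model's own log-partition).
#'
#' @inheritParams combine_models
#' @return list with `labels`, `score` (winning model's log-probability), and
#'   `source` (`"unary"` or `"pairwise"`).
#' @export
ensemble_decode <- function(U, A, V) {
  pu <- unary_potentials(U, A)
  pp <- pairwise_potentials(V, n_pos = nrow(as.matrix(U)))
  du <- viterbi_decode(pu)
  dp <- viterbi_decode(pp)
  lpu <- du$score - log_partition(pu)
  lpp <- dp$score - log_partition(pp)
  if (lpu >= lpp) list(labels = du$labels, score = lpu, source = "unary")
  else list(labels = dp$labels, score = lpp, source = "pairwise")
}

#' Exhaustive enumeration oracle
#'
#' Enumerates all `L^N` label sequences; used as the independent oracle for
#' the forward algorithm and Viterbi decoding in tests.
#'
#' @inheritParams sequence_score
#' @param max_size refuse instances with more than this many sequences.
#' @return list with `logZ`, `best_sequence`, `best_score`, and
#'   `probabilities` (vector over all sequences, sums to 1).
#' @export
brute_force_enumerate <- function(potentials, max_size = 20000L) {
  n <- n_positions(potentials); l <- n_labels(potentials)
  if (l^n > max_size)
    stop("instance too large to enumerate: L^N = ", l^n)
  grid <- as.matrix(expand.grid(rep(list(seq_len(l)), n))[, n:1, drop = FALSE])
  scores <- apply(grid, 1L, function(y) sequence_score(potentials, y))
  logZ <- log_sum_exp(scores)
  best <- which.max(scores)
  list(logZ = logZ,
       best_sequence = unname(grid[best, ]),
       best_score = unname(scores[best]),
       probabilities = exp(scores - logZ))
}
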