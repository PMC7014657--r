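# Reference (plain R) implementations of the potential networks: BiLSTM
# encoding, the unary binding layer, and the bilinear pairwise interaction
# with its binding layer.  The compiled training core implements the same
# maps; these functions define the contract and serve as its cross-check.

sigmoid <- function(x) 1 / (1 + exp(-x))

elu <- function(x) ifelse(x > 0, x, exp(x) - 1)

lstm_run <- function(X, W, U, b) {
  # X: N x d_e (rows = tokens); returns N x H
  H <- ncol(U)
  n <- nrow(X)
  out <- matrix(0, n, H)
  h <- numeric(H); cc <- numeric(H)
  for (t in seq_len(n)) {
    z <- as.vector(W %*% X[t, ] + U %*% h + b)
    i <- sigmoid(z[1:H])
    f <- sigmoid(z[(H + 1):(2 * H)])
    o <- sigmoid(z[(2 * H + 1):(3 * H)])
    g <- tanh(z[(3 * H + 1):(4 * H)])
    cc <- f * cc + i * g
    h <- o * tanh(cc)
    out[t, ] <- h
  }
  out
}

#' BiLSTM encoding of a token-embedding sequence
#'
#' Runs one LSTM left-to-right and one right-to-left and concatenates their
#' hidden states per position.
#'
#' @param embeds N x d_e matrix of token embeddings (rows = tokens).
#' @param params list with elements `fw` and `bw`, each a list of gate
#'   parameters `W` (4H x d_e), `U` (4H x H), `b` (4H); gate order is
#'   input, forget, output, candidate.
#' @return N x d matrix (`d = 2H`); columns `1:H` are the forward states.
#' @export
bilstm_encode <- function(embeds, params) {
  embeds <- as.matrix(embeds)
  if (ncol(embeds) != ncol(params$fw$W))
    stop("embedding dimension ", ncol(embeds), " does not match BiLSTM input ",
         ncol(params$fw$W))
  hf <- lstm_run(embeds, params$fw$W, params$fw$U, params$fw$b)
  hb <- lstm_run(embeds[rev(seq_len(nrow(embeds))), , drop = FALSE],
                 params$bw$W, params$bw$U, params$bw$b)
  cbind(hf, hb[rev(seq_len(nrow(hb))), , drop = FALSE])
}

#' Unary binding layer
#'
#' Projects hidden states to per-token label scores through two linear maps
#' with an activation and a skip connection:
#' `U_i = W2 (sigma(W1 h_i + b1) + h_i) + b2`, applied independently per
#' position.
#'
#' @param h N x d matrix of hidden states.
#' @param params list with `W1` (d x d), `b1` (d), `W2` (L x d), `b2` (L).
#' @param activation activation function (default ELU).
#' @return N x L matrix of unary scores.
#' @export
unary_binding <- function(h, params, activation = elu) {
  h <- as.matrix(h)
  if (ncol(h) != ncol(params$W1)) stop("hidden dimension mismatch")
  inner <- activation(h %*% t(params$W1) +
                        matrix(params$b1, nrow(h), length(params$b1),
                               byrow = TRUE)) + h
  inner %*% t(params$W2) +
    matrix(params$b2, nrow(h), length(params$b2), byrow = TRUE)
}

#' Bilinear pairwise interaction
#'
#' Low-rank factorized interaction of two neighboring hidden states:
#' `f = H ((Q1 h_prev) o (Q2 h_curr))` with `o` the Hadamard product.  The
#' factorization stands in for a full three-way tensor.
#'
#' @param h_prev,h_curr length-d hidden state vectors.
#' @param params list with `Q1` (c x d), `Q2` (c x d), `H` (m x c).
#' @return length-m feature vector.
#' @export
pairwise_interaction <- function(h_prev, h_curr, params) {
  if (length(h_prev) != ncol(params$Q1) || length(h_curr) != ncol(params$Q2))
    stop("hidden dimension mismatch")
  as.vector(params$H %*% ((params$Q1 %*% h_prev) * (params$Q2 %*% h_curr)))
}

#' Pairwise binding layer
#'
#' Maps a pairwise feature vector to an L x L slice of edge scores through
#' the same two-linear-maps-with-skip structure as the unary binding layer.
#' The flat L^2 output is laid out with the PREVIOUS label as the major
#' index: `v[(j-1)*L + k]` scores the pair (previous = j, current = k).
#'
#' @param f length-m pairwise feature vector.
#' @param params list with `W1` (m x m), `b1` (m), `W2` (L^2 x m), `b2`
#'   (L^2).
#' @param activation activation function (default ELU).
#' @return L x L matrix; rows index the previous label.
#' @export
pairwise_binding <- function(f, params, activation = elu) {
  if (length(f) != ncol(params$W1)) stop("feature dimension mismatch")
  v <- as.vector(params$W2 %*% (activation(params$W1 %*% f + params$b1) + f) +
                   params$b2)
  L <- as.integer(sqrt(length(v)))
  matrix(v, L, L, byrow = TRUE)             # previous label = row
}

# effective matrix of a weight-normalized parameterization
weight_norm_matrix <- function(v, g) {
  rn <- sqrt(rowSums(v^2))
  v * (g / rn)
}

# assemble plain-R network parameters (effective matrices) from a trained
# parameter list, for cross-checking the compiled path
effective_network_params <- function(params, share_bilstm = FALSE) {
  pre <- if (share_bilstm) "u" else "p"
  list(
    u_lstm = list(fw = list(W = params$u_fw_W, U = params$u_fw_U,
                            b = params$u_fw_b),
                  bw = list(W = params$u_bw_W, U = params$u_bw_U,
                            b = params$u_bw_b)),
    p_lstm = list(fw = list(W = params[[paste0(pre, "_fw_W")]],
                            U = params[[paste0(pre, "_fw_U")]],
                            b = params[[paste0(pre, "_fw_b")]]),
                  bw = list(W = params[[paste0(pre, "_bw_W")]],
                            U = params[[paste0(pre, "_bw_U")]],
                            b = params[[paste0(pre, "_bw_b")]])),
    u_bind = list(W1 = weight_norm_matrix(params$u_W1_v, params$u_W1_g),
                  b1 = params$u_b1,
                  W2 = weight_norm_matrix(params$u_W2_v, params$u_W2_g),
                  b2 = params$u_b2),
    bilinear = list(Q1 = params$Q1, Q2 = params$Q2, H = params$Hm),
    p_bind = list(W1 = weight_norm_matrix(params$p_W1_v, params$p_W1_g),
                  b1 = params$p_b1,
                  W2 = weight_norm_matrix(params$p_W2_v, params$p_W2_g),
                  b2 = params$p_b2))
}
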