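# Model state: parameter initialization, token indexing, potential
# computation, and decoding front-ends over the compiled core.

#' Training / model configuration
#'
#' Bundles the optimization regimen (Adam, learning rate 0.001, L2 decay
#' 1e-5, gradient-norm clipping at 5, dropout keep probability 0.5 on the
#' binding-layer inputs, minibatch size 10, at most 50 epochs) with the model
#' sizes: BiLSTM output dimension `d` per network, bilinear factor rank `c`,
#' pairwise feature dimension `m`.
#'
#' @param learning_rate Adam step size.
#' @param l2_decay L2 penalty factor on weight matrices.
#' @param grad_clip_norm global gradient L2-norm ceiling.
#' @param dropout_keep keep probability for binding-layer input dropout.
#' @param minibatch_size sentences per gradient step.
#' @param max_epochs epoch budget.
#' @param seed RNG seed controlling initialization, shuffling and dropout.
#' @param d BiLSTM output dimension (even; each direction contributes `d/2`).
#' @param c bilinear interaction rank.
#' @param m pairwise feature dimension.
#' @param share_bilstm share one BiLSTM between the unary and pairwise
#'   networks (ablation variant) instead of the default separate encoders.
#' @param trainable_dim dimension of the trainable lookup table used when no
#'   pretrained embedding table is supplied.
#' @param ln_eps layer-normalization variance floor.
#' @return A `train_config` list.
#' @export
train_config <- function(learning_rate = 0.001, l2_decay = 1e-5,
                         grad_clip_norm = 5.0, dropout_keep = 0.5,
                         minibatch_size = 10L, max_epochs = 50L, seed = 1L,
                         d = 300L, c = 128L, m = 64L, share_bilstm = FALSE,
                         trainable_dim = 32L, ln_eps = 1e-5) {
  cfg <- list(learning_rate = learning_rate, l2_decay = l2_decay,
              grad_clip_norm = grad_clip_norm, dropout_keep = dropout_keep,
              minibatch_size = as.integer(minibatch_size),
              max_epochs = as.integer(max_epochs), seed = as.integer(seed),
              d = as.integer(d), c = as.integer(c), m = as.integer(m),
              share_bilstm = isTRUE(share_bilstm),
              trainable_dim = as.integer(trainable_dim), ln_eps = ln_eps)
  stopifnot(cfg$learning_rate > 0, cfg$l2_decay >= 0, cfg$grad_clip_norm > 0,
            cfg$dropout_keep > 0, cfg$dropout_keep <= 1,
            cfg$minibatch_size >= 1L, cfg$max_epochs >= 1L,
            cfg$d %% 2L == 0L, cfg$d >= 2L, cfg$c >= 1L, cfg$m >= 1L)
  class(cfg) <- "train_config"
  cfg
}

glorot <- function(nrow, ncol) {
  b <- sqrt(6 / (nrow + ncol))
  matrix(stats::runif(nrow * ncol, -b, b), nrow, ncol)
}

#' Initialize model parameters
#'
#' Weight matrices use the Glorot uniform initializer
#' (`Uniform(+-sqrt(6/(fan_in+fan_out)))`), biases start at zero, layer-norm
#' gains at one.  The weight-normalized binding matrices are stored as a
#' direction matrix `*_v` and row gains `*_g` initialized to the row norms,
#' so the effective matrix initially equals its Glorot draw.  The static
#' transition matrix `A` is initialized as a weight matrix.
#'
#' @param n_vocab vocabulary size of the lookup table (rows of `E`).
#' @param d_w lookup-vector dimension.
#' @param d_ctx contextual-vector dimension (0 when disabled).
#' @param L number of labels.
#' @param config a [train_config()].
#' @param seed RNG seed (defaults to `config$seed`).
#' @return named list of parameter arrays.
#' @export
init_params <- function(n_vocab, d_w, d_ctx, L, config, seed = config$seed) {
  set.seed(seed)
  d <- config$d; H <- d %/% 2L; cc <- config$c; m <- config$m
  d_e <- d_w + d_ctx
  wn <- function(nrow, ncol) {
    v <- glorot(nrow, ncol)
    list(v = v, g = sqrt(rowSums(v^2)))
  }
  lstm <- function() list(W = glorot(4L * H, d_e), U = glorot(4L * H, H),
                          b = rep(0, 4L * H))
  p <- list(E = glorot(n_vocab, d_w),
            ln_g = rep(1, d_e), ln_b = rep(0, d_e))
  for (net in c("u", "p")) {
    if (net == "p" && config$share_bilstm) next
    for (dir in c("fw", "bw")) {
      l <- lstm()
      p[[paste0(net, "_", dir, "_W")]] <- l$W
      p[[paste0(net, "_", dir, "_U")]] <- l$U
      p[[paste0(net, "_", dir, "_b")]] <- l$b
    }
  }
  w1u <- wn(d, d); w2u <- wn(L, d)
  p$u_W1_v <- w1u$v; p$u_W1_g <- w1u$g; p$u_b1 <- rep(0, d)
  p$u_W2_v <- w2u$v; p$u_W2_g <- w2u$g; p$u_b2 <- rep(0, L)
  p$A <- glorot(L, L)
  p$Q1 <- glorot(cc, d); p$Q2 <- glorot(cc, d); p$Hm <- glorot(m, cc)
  w1p <- wn(m, m); w2p <- wn(L * L, m)
  p$p_W1_v <- w1p$v; p$p_W1_g <- w1p$g; p$p_b1 <- rep(0, m)
  p$p_W2_v <- w2p$v; p$p_W2_g <- w2p$g; p$p_b2 <- rep(0, L * L)
  p
}

cpp_config <- function(model) {
  list(L = length(model$label_set), d = model$config$d, c = model$config$c,
       m = model$config$m, d_e = model$d_e,
       share_bilstm = model$config$share_bilstm,
       trainable_embeddings = model$trainable_embeddings,
       dropout_keep = model$config$dropout_keep,
       ln_eps = model$config$ln_eps)
}

token_ids <- function(model, tokens) {
  idx <- match(tokens, model$vocab)
  idx[is.na(idx)] <- match(UNK_TOKEN, model$vocab)
  idx
}

label_ids <- function(model, labels) {
  idx <- match(labels, model$label_set)
  if (anyNA(idx))
    stop("labels not in the model's label set: ",
         paste(unique(labels[is.na(idx)]), collapse = ", "))
  idx
}

sentence_ctx <- function(model, key) {
  if (is.null(model$store)) return(NULL)
  ctx <- model$store$matrices[[key]]
  if (is.null(ctx)) stop("sentence key ", key, " not in contextual store")
  ctx
}

#' Compute neural node and edge potentials for one sentence
#'
#' Runs the unary network (BiLSTM + binding layer) and the pairwise network
#' (BiLSTM + bilinear interaction + binding layer) over the sentence.
#'
#' @param model a trained or freshly initialized model (see [train()]).
#' @param sentence a [labeled_sentence()].
#' @param key sentence identifier in the contextual store, when one is used.
#' @return list with `U` (N x L unary scores) and `V` ((N-1) x L x L dynamic
#'   transition scores; previous label is the first label index).
#' @export
model_potentials <- function(model, sentence, key = NULL) {
  ids <- token_ids(model, sentence$tokens)
  ctx <- if (is.null(key)) NULL else sentence_ctx(model, key)
  out <- cpp_potentials(as.integer(ids), ctx, model$params, cpp_config(model))
  L <- length(model$label_set)
  n <- length(ids)
  V <- array(0, dim = c(max(n - 1L, 0L), L, L))
  if (n > 1L) V <- aperm(out$V, c(3L, 1L, 2L))
  list(U = out$U, V = V)
}

decode_modes <- c("combined", "unary", "pairwise", "ensemble")

decode_sentence <- function(model, sentence, mode, key = NULL) {
  ids <- token_ids(model, sentence$tokens)
  ctx <- if (is.null(key)) NULL else sentence_ctx(model, key)
  out <- cpp_potentials(as.integer(ids), ctx, model$params, cpp_config(model))
  L <- length(model$label_set)
  n <- length(ids)
  nodes <- t(out$U)                                    # L x N
  Acube <- array(model$params$A, dim = c(L, L, max(n - 1L, 0L)))
  Vcube <- if (n > 1L) out$V else array(0, dim = c(L, L, 0L))
  if (mode == "combined") {
    cpp_viterbi(nodes, Vcube + Acube)$labels
  } else if (mode == "unary") {
    cpp_viterbi(nodes, Acube)$labels
  } else if (mode == "pairwise") {
    cpp_viterbi(matrix(0, L, n), Vcube)$labels
  } else { # ensemble: per-model vote by own log-probability
    du <- cpp_viterbi(nodes, Acube)
    dp <- cpp_viterbi(matrix(0, L, n), Vcube)
    lpu <- du$score - cpp_log_partition(nodes, Acube)
    lpp <- dp$score - cpp_log_partition(matrix(0, L, n), Vcube)
    if (lpu >= lpp) du$labels else dp$labels
  }
}

#' Predict label sequences for a corpus
#'
#' Decodes every sentence with the Viterbi algorithm under the selected
#' potentials: `"combined"` (the product of models: nodes `U`, edges
#' `V + A`), `"unary"` (static transitions only: `U` and `A`),
#' `"pairwise"` (edges-only: `V`), or `"ensemble"` (per-model vote between
#' the unary and pairwise decodes by their own log-probabilities).
#'
#' @param model a trained model.
#' @param corpus a [ner_corpus()].
#' @param mode decoding mode, see above.
#' @param keys optional sentence keys into the contextual store.
#' @return a [ner_corpus()] with predicted labels (tokens unchanged).
#' @export
predict_corpus <- function(model, corpus, mode = "combined", keys = NULL) {
  mode <- match.arg(mode, decode_modes)
  sentences <- lapply(seq_along(corpus), function(i) {
    s <- corpus[[i]]
    y <- decode_sentence(model, s, mode,
                         key = if (is.null(keys)) NULL else keys[[i]])
    labeled_sentence(s$tokens, model$label_set[y])
  })
  ner_corpus(sentences, label_set = model$label_set,
             scheme = attr(corpus, "scheme"), split = attr(corpus, "split"))
}

#' Save / load a model
#'
#' Serializes the full model state (parameters, optimizer state, RNG state,
#' configuration, vocabulary) so that training can resume bit-exactly.
#'
#' @param model a model object.
#' @param path file path.
#' @export
save_model <- function(model, path) saveRDS(model, path)

#' @rdname save_model
#' @export
load_model <- function(path) readRDS(path)
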