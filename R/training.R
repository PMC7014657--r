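# Joint two-CRF training: the objective is the summed negative
# log-likelihood of the gold sequence under the unary CRF and under the
# pairwise CRF (each network is penalized by its own prediction error),
# averaged over the minibatch, plus an L2 penalty on the weight matrices.
# Optimization follows the standard regimen: Adam, gradient-norm clipping,
# dropout on the binding-layer inputs, best-epoch selection on dev F1.

L2_WEIGHT_NAMES <- c("u_fw_W", "u_fw_U", "u_bw_W", "u_bw_U",
                     "p_fw_W", "p_fw_U", "p_bw_W", "p_bw_U",
                     "Q1", "Q2", "Hm",
                     # for weight-normalized matrices |W|_F^2 = sum(g^2),
                     # so the penalty acts on the row gains
                     "u_W1_g", "u_W2_g", "p_W1_g", "p_W2_g")

l2_penalty <- function(params, l2_decay) {
  nm <- intersect(L2_WEIGHT_NAMES, names(params))
  l2_decay * sum(vapply(nm, function(n) sum(params[[n]]^2), numeric(1)))
}

new_model <- function(corpus, config, embeddings = NULL) {
  labels <- label_set(corpus)
  L <- length(labels)
  if (L < 2L) stop("need at least 2 labels")
  store <- embeddings$store
  d_ctx <- if (is.null(store)) 0L else store$d_ctx
  if (is.null(embeddings$table)) {
    vocab <- sort(unique(unlist(lapply(corpus, `[[`, "tokens"))))
    vocab <- c(vocab, UNK_TOKEN)
    d_w <- config$trainable_dim
    trainable <- TRUE
    E <- NULL
  } else {
    vocab <- rownames(embeddings$table$vectors)
    d_w <- embeddings$table$d_w
    trainable <- FALSE
    E <- embeddings$table$vectors
  }
  params <- init_params(length(vocab), d_w, d_ctx, L, config)
  if (!is.null(E)) params$E <- unname(E)
  structure(list(params = params, config = config, label_set = labels,
                 vocab = vocab, d_e = d_w + d_ctx,
                 trainable_embeddings = trainable, store = store,
                 opt = list(m = list(), v = list(), t = 0L),
                 epoch = 0L, best_f1 = -Inf, best_epoch = NA_integer_,
                 log = NULL),
            class = "dyntrans_model")
}

#' @export
print.dyntrans_model <- function(x, ...) {
  cat(sprintf(paste0("<dyntrans_model> L=%d labels, d=%d, c=%d, m=%d, ",
                     "|V|=%d, epoch %d%s\n"),
              length(x$label_set), x$config$d, x$config$c, x$config$m,
              length(x$vocab), x$epoch,
              if (is.na(x$best_epoch)) ""
              else sprintf(" (best dev F1 %.2f @ epoch %d)",
                           x$best_f1, x$best_epoch)))
  invisible(x)
}

batch_arrays <- function(model, batch, keys = NULL) {
  ids <- lapply(batch, function(s) as.integer(token_ids(model, s$tokens)))
  y <- lapply(batch, function(s) as.integer(label_ids(model, s$labels)))
  ctx <- if (is.null(model$store)) list() else lapply(keys, sentence_ctx,
                                                      model = model)
  list(ids = ids, y = y, ctx = ctx)
}

#' Joint two-CRF loss of a minibatch
#'
#' The per-sentence loss is the negative log-likelihood of the gold labels
#' under the unary CRF plus that under the pairwise CRF; sentence losses are
#' averaged over the batch and an L2 penalty on the weight matrices is
#' added.  Dropout is off (evaluation semantics).
#'
#' @param model a model object.
#' @param batch list of [labeled_sentence()]s (or a [ner_corpus()]).
#' @param keys optional contextual-store keys.
#' @return scalar loss, with attributes `nll_u` and `nll_p` (batch means).
#' @export
joint_loss <- function(model, batch, keys = NULL) {
  ba <- batch_arrays(model, batch, keys)
  out <- cpp_batch_loss_grad(ba$ids, ba$ctx, ba$y, model$params,
                             cpp_config(model), FALSE, FALSE)
  loss <- mean(out$nll_u + out$nll_p) +
    l2_penalty(model$params, model$config$l2_decay)
  structure(loss, nll_u = mean(out$nll_u), nll_p = mean(out$nll_p))
}

# loss gradient matching joint_loss (dropout optional); used by the training
# loop and by finite-difference tests
joint_loss_grad <- function(model, batch, keys = NULL, dropout = FALSE) {
  ba <- batch_arrays(model, batch, keys)
  out <- cpp_batch_loss_grad(ba$ids, ba$ctx, ba$y, model$params,
                             cpp_config(model), dropout, TRUE)
  B <- length(batch)
  grads <- out$grads
  for (nm in names(grads)) {              # mirror each parameter's shape
    g <- grads[[nm]] / B
    if (is.null(dim(model$params[[nm]]))) dim(g) <- NULL
    grads[[nm]] <- g
  }
  for (nm in intersect(L2_WEIGHT_NAMES, names(grads)))
    grads[[nm]] <- grads[[nm]] + 2 * model$config$l2_decay * model$params[[nm]]
  list(grads = grads,
       nll_u = mean(out$nll_u), nll_p = mean(out$nll_p),
       loss = mean(out$nll_u + out$nll_p) +
         l2_penalty(model$params, model$config$l2_decay))
}

#' Clip gradients by global L2 norm
#'
#' When the L2 norm over all entries of all gradient arrays exceeds
#' `max_norm`, every array is rescaled by `max_norm / norm`; otherwise the
#' gradients are returned unchanged.
#'
#' @param gradients named list of numeric arrays.
#' @param max_norm positive norm ceiling.
#' @return the (possibly rescaled) gradient list.
#' @export
clip_gradients <- function(gradients, max_norm) {
  for (nm in names(gradients))
    if (!all(is.finite(gradients[[nm]])))
      stop("non-finite gradient in parameter ", nm)
  total <- sqrt(sum(vapply(gradients, function(g) sum(g^2), numeric(1))))
  if (total > max_norm)
    gradients <- lapply(gradients, function(g) g * (max_norm / total))
  gradients
}

adam_step <- function(params, grads, opt, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  opt$t <- opt$t + 1L
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(opt$m[[nm]])) {
      opt$m[[nm]] <- g * 0
      opt$v[[nm]] <- g * 0
    }
    opt$m[[nm]] <- beta1 * opt$m[[nm]] + (1 - beta1) * g
    opt$v[[nm]] <- beta2 * opt$v[[nm]] + (1 - beta2) * g^2
    mhat <- opt$m[[nm]] / (1 - beta1^opt$t)
    vhat <- opt$v[[nm]] / (1 - beta2^opt$t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, opt = opt)
}

#' Train the joint two-CRF model
#'
#' Runs up to `config$max_epochs` epochs of seeded-shuffle minibatch Adam
#' with dropout, gradient clipping and L2 regularization.  After every epoch
#' the combined model (product of the unary and pairwise CRFs) is evaluated
#' on the dev corpus by entity-level F1 and the best-epoch parameters are
#' retained; with no dev corpus the last epoch is kept.
#'
#' @param corpus training [ner_corpus()] in IOBES.
#' @param dev_corpus optional development corpus for model selection.
#' @param config a [train_config()].
#' @param embeddings optional list with `table` (an [embedding_table()];
#'   frozen during training) and `store` (a [contextual_store()]).  With
#'   neither, a trainable lookup table of dimension `config$trainable_dim`
#'   is built from the training vocabulary.
#' @param keys,dev_keys contextual-store keys per sentence, when used.
#' @param resume a model returned by an earlier [train()] call (or
#'   [load_model()]); training continues bit-exactly from its optimizer and
#'   RNG state up to `config$max_epochs` total epochs.
#' @param verbose print per-epoch progress.
#' @return A `dyntrans_model` whose `$params` are the selected parameters and
#'   whose `$log` holds per-epoch training NLLs and dev F1.
#' @export
train <- function(corpus, dev_corpus = NULL, config = train_config(),
                  embeddings = NULL, keys = NULL, dev_keys = NULL,
                  resume = NULL, verbose = FALSE) {
  if (length(corpus) == 0L) stop("empty training corpus")
  if (tagging_scheme(corpus) != "IOBES")
    stop("training expects an IOBES corpus; convert first")
  if (is.null(resume)) {
    model <- new_model(corpus, config, embeddings) # seeds the RNG stream
    last_params <- model$params
  } else {
    model <- resume
    model$config$max_epochs <- config$max_epochs
    config <- model$config
    last_params <- model$last_params
    assign(".Random.seed", model$rng_state, envir = globalenv())
  }
  n <- length(corpus)
  B <- config$minibatch_size
  log_rows <- list()
  epochs <- if (model$epoch < config$max_epochs)
    (model$epoch + 1L):config$max_epochs else integer()
  for (epoch in epochs) {
    ord <- sample.int(n)
    sum_u <- 0; sum_p <- 0; nb <- 0L
    for (start in seq(1L, n, by = B)) {
      idx <- ord[start:min(start + B - 1L, n)]
      work <- model
      work$params <- last_params
      step <- joint_loss_grad(work, unclass(corpus)[idx],
                              keys = if (is.null(keys)) NULL else keys[idx],
                              dropout = TRUE)
      if (length(model$opt$m) == 0L) {
        model$opt$m <- lapply(step$grads, function(g) g * 0)
        model$opt$v <- lapply(step$grads, function(g) g * 0)
      }
      model$opt$t <- model$opt$t + 1L
      upd <- cpp_adam_step(last_params, step$grads, model$opt$m, model$opt$v,
                           model$opt$t, config$learning_rate,
                           config$grad_clip_norm, 0.9, 0.999, 1e-8)
      last_params <- upd$params
      model$opt$m <- upd$m
      model$opt$v <- upd$v
      sum_u <- sum_u + step$nll_u
      sum_p <- sum_p + step$nll_p
      nb <- nb + 1L
    }
    model$epoch <- epoch
    dev_f1 <- NA_real_
    if (!is.null(dev_corpus)) {
      eval_model <- model
      eval_model$params <- last_params
      pred <- predict_corpus(eval_model, dev_corpus, mode = "combined",
                             keys = dev_keys)
      dev_f1 <- entity_f1(dev_corpus, pred)$f1
      if (dev_f1 > model$best_f1) {
        model$best_f1 <- dev_f1
        model$best_epoch <- epoch
        model$params <- last_params
      }
    }
    log_rows[[length(log_rows) + 1L]] <-
      data.frame(epoch = epoch, nll_u = sum_u / nb, nll_p = sum_p / nb,
                 dev_f1 = dev_f1)
    if (verbose)
      message(sprintf("epoch %3d  nll_u %.4f  nll_p %.4f  dev F1 %s",
                      epoch, sum_u / nb, sum_p / nb,
                      ifelse(is.na(dev_f1), "-", sprintf("%.2f", dev_f1))))
  }
  if (is.null(dev_corpus) || is.na(model$best_epoch))
    model$params <- last_params
  model$last_params <- last_params
  model$rng_state <- get(".Random.seed", envir = globalenv())
  model$log <- rbind(model$log, do.call(rbind, log_rows))
  model
}
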