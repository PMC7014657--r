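test_that("parameter initialization follows Glorot with zero biases", {
  tm <- tiny_model()
  p <- tm$model$params
  for (nm in grep("_b$|_b1$|_b2$|ln_b", names(p), value = TRUE))
    expect_true(all(p[[nm]] == 0), label = nm)
  expect_true(all(p$ln_g == 1))
  set.seed(9)
  W <- dyntrans:::glorot(10, 30)
  bound <- sqrt(6 / 40)
  expect_true(all(abs(W) <= bound))
  expect_gt(max(abs(W)), 0.8 * bound)      # actually fills the range
  # reproducibility of the full state
  cfg <- tm$config
  p1 <- init_params(20, 6, 0, 9, cfg, seed = 4)
  p2 <- init_params(20, 6, 0, 9, cfg, seed = 4)
  expect_identical(p1, p2)
  # weight-normalized matrices start equal to their Glorot draw
  W1 <- dyntrans:::weight_norm_matrix(p1$u_W1_v, p1$u_W1_g)
  expect_equal(W1, p1$u_W1_v, tolerance = 1e-12)
})

test_that("the training configuration carries the published regimen", {
  cfg <- train_config()
  expect_equal(cfg$learning_rate, 0.001)
  expect_equal(cfg$l2_decay, 1e-5)
  expect_equal(cfg$grad_clip_norm, 5.0)
  expect_equal(cfg$dropout_keep, 0.5)
  expect_equal(cfg$minibatch_size, 10L)
  expect_equal(cfg$max_epochs, 50L)
  expect_error(train_config(d = 7), "d")
})

test_that("gradient clipping rescales by the global norm", {
  g <- list(a = c(3, 4), b = matrix(c(5, 0, 0, sqrt(50)), 2, 2))
  # norm = sqrt(9+16+25+50) = 10
  clipped <- clip_gradients(g, 5)
  expect_equal(clipped$a, c(1.5, 2))
  expect_equal(clipped$b, g$b / 2)
  small <- list(a = c(3, 0), b = c(0, 0))
  expect_identical(clip_gradients(small, 5), small)
  zero <- list(a = c(0, 0))
  expect_identical(clip_gradients(zero, 5), zero)
  expect_error(clip_gradients(list(bad = c(1, NaN)), 5), "bad")
})

test_that("a zero-parameter model yields the uniform joint loss", {
  tm <- tiny_model(d = 4, c = 2, m = 2)
  model <- tm$model
  for (nm in names(model$params))
    if (!grepl("_v$", nm)) model$params[[nm]][] <- 0
  # zero gains make the weight-normalized binding matrices zero; with all
  # other weights zero both CRFs are uniform over L^N sequences
  s <- labeled_sentence(sprintf("w%d", 1:4),
                        c("O", "S-TypeA", "O", "S-TypeB"))
  L <- length(model$label_set)
  loss <- joint_loss(model, list(s))
  expect_equal(as.numeric(loss), 2 * 4 * log(L), tolerance = 1e-10)
  expect_equal(attr(loss, "nll_u"), 4 * log(L), tolerance = 1e-10)
  expect_equal(attr(loss, "nll_p"), 4 * log(L), tolerance = 1e-10)
})

test_that("both negative log-likelihood terms are always non-negative", {
  set.seed(61)
  for (rep in 1:5) {
    tm <- tiny_model(seed = rep, n = 4)
    loss <- joint_loss(tm$model, unclass(tm$corpus))
    expect_gte(attr(loss, "nll_u"), 0)
    expect_gte(attr(loss, "nll_p"), 0)
    expect_gte(as.numeric(loss), 0)
  }
})

test_that("the fused optimizer step equals clip + Adam done in R", {
  set.seed(62)
  tm <- tiny_model()
  model <- tm$model
  step <- dyntrans:::joint_loss_grad(model, unclass(tm$corpus)[1:3])
  m0 <- lapply(step$grads, function(g) g * 0)
  v0 <- m0
  r_clipped <- clip_gradients(step$grads, 0.5)   # force clipping to engage
  r_upd <- dyntrans:::adam_step(model$params, r_clipped,
                                list(m = m0, v = v0, t = 0L), 0.01)
  c_upd <- dyntrans:::cpp_adam_step(model$params, step$grads, m0, v0, 1L,
                                    0.01, 0.5, 0.9, 0.999, 1e-8)
  for (nm in names(step$grads)) {
    expect_equal(c_upd$params[[nm]], r_upd$params[[nm]], tolerance = 1e-12,
                 label = nm)
    expect_equal(c_upd$m[[nm]], r_upd$opt$m[[nm]], tolerance = 1e-12)
  }
})

test_that("one small Adam step decreases the joint loss", {
  set.seed(63)
  ok <- 0L
  for (rep in 1:20) {
    tm <- tiny_model(seed = 200 + rep, n = 2, d = 6)
    model <- tm$model
    batch <- unclass(tm$corpus)[1]
    before <- as.numeric(joint_loss(model, batch))
    step <- dyntrans:::joint_loss_grad(model, batch)
    upd <- dyntrans:::adam_step(model$params, step$grads,
                                list(m = lapply(step$grads, function(g) g * 0),
                                     v = lapply(step$grads, function(g) g * 0),
                                     t = 0L), 1e-4)
    model$params <- upd$params
    after <- as.numeric(joint_loss(model, batch))
    if (after < before) ok <- ok + 1L
  }
  expect_equal(ok, 20L)
})

test_that("training is deterministic, bounded by max_epochs, and learns", {
  corp <- generate_corpus(tiny_generator(seed = 8, n = 60))
  cfg <- train_config(d = 8, c = 4, m = 4, seed = 3, trainable_dim = 6,
                      max_epochs = 3L)
  m1 <- train(corp, config = cfg)
  m2 <- train(corp, config = cfg)
  expect_identical(m1$params, m2$params)
  expect_identical(m1$log, m2$log)
  expect_lte(max(m1$log$epoch), cfg$max_epochs)
  expect_lt(m1$log$nll_u[3] + m1$log$nll_p[3],
            m1$log$nll_u[1] + m1$log$nll_p[1])
  expect_error(train(corp[integer(0)], config = cfg), "empty")
})

test_that("both per-network losses trend downward during training", {
  corp <- generate_corpus(tiny_generator(seed = 9, n = 120))
  cfg <- train_config(d = 16, c = 8, m = 6, seed = 2, trainable_dim = 8,
                      max_epochs = 6L)
  model <- train(corp, config = cfg)
  rho_u <- stats::cor(model$log$epoch, model$log$nll_u, method = "spearman")
  rho_p <- stats::cor(model$log$epoch, model$log$nll_p, method = "spearman")
  expect_lt(rho_u, 0)
  expect_lt(rho_p, 0)
})

test_that("checkpointed training resumes bit-exactly", {
  corp <- generate_corpus(tiny_generator(seed = 10, n = 40))
  sp <- make_split(corp, c(0.6, 0.2, 0.2), seed = 1)
  cfg3 <- train_config(d = 8, c = 4, m = 4, seed = 5, trainable_dim = 6,
                       max_epochs = 3L)
  straight <- train(sp$train, sp$dev, cfg3)
  cfg1 <- cfg3; cfg1$max_epochs <- 1L
  part <- train(sp$train, sp$dev, cfg1)
  f <- withr::local_tempfile()
  save_model(part, f)
  resumed <- train(sp$train, sp$dev, cfg3, resume = load_model(f))
  expect_identical(resumed$last_params, straight$last_params)
  expect_identical(resumed$params, straight$params)
  expect_equal(resumed$log, straight$log)
})

test_that("dev-based selection retains the best epoch", {
  corp <- generate_corpus(tiny_generator(seed = 12, n = 60))
  sp <- make_split(corp, c(0.7, 0.15, 0.15), seed = 2)
  cfg <- train_config(d = 8, c = 4, m = 4, seed = 1, trainable_dim = 6,
                      max_epochs = 3L)
  model <- train(sp$train, sp$dev, cfg)
  expect_false(is.na(model$best_epoch))
  expect_equal(model$best_f1, max(model$log$dev_f1))
})
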