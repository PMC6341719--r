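test_that("the learning-rate schedule halves every configured interval", {
  cfg <- training_config()
  expect_equal(lr_at(0, cfg), 1e-5)
  expect_equal(lr_at(4999, cfg), 1e-5)
  expect_equal(lr_at(5000, cfg), 5e-6)
  expect_equal(lr_at(12345, cfg), 2.5e-6)
  expect_error(lr_at(-1, cfg), "non-negative")
})

test_that("SGD-momentum reduces to its closed-form special cases", {
  p <- list(w = matrix(1:4 / 10, 2, 2), b = c(0.5, -0.5))
  v0 <- lapply(p, function(x) x * 0)
  zg <- lapply(p, function(x) x * 0)
  # zero grads, zero decay, zero velocity -> unchanged
  st <- sgd_momentum_step(p, zg, v0, lr = 0.1, momentum = 0.9,
                          weight_decay = 0)
  expect_identical(st$params, p)
  # momentum 0, decay 0 -> vanilla SGD
  g <- list(w = matrix(1, 2, 2), b = c(2, 2))
  st <- sgd_momentum_step(p, g, v0, lr = 0.1, momentum = 0,
                          weight_decay = 0)
  expect_equal(st$params$w, p$w - 0.1 * g$w)
  expect_equal(st$params$b, p$b - 0.1 * g$b)
  # zero grads + decay w -> param * (1 - lr * w) after one step
  st <- sgd_momentum_step(p, zg, v0, lr = 0.1, momentum = 0.99,
                          weight_decay = 0.5)
  expect_equal(st$params$w, p$w * (1 - 0.1 * 0.5))
  # non-finite gradient is caught
  bad <- list(w = matrix(NaN, 2, 2), b = c(0, 0))
  expect_error(sgd_momentum_step(p, bad, v0, 0.1, 0.9, 0), "non-finite")
})

test_that("alternation performs exactly ratio adversary updates per generator update", {
  spec <- tiny_spec()
  corpus <- build_corpus(2L, spec, seed = 1L)
  cfg <- desk_training_config(iterations = 4L, ratio = 3L, batch_size = 2L,
                              seed = 5L)
  fit <- train_alternating(corpus, tiny_gen_arch(), tiny_adv_arch(), cfg)
  tab <- table(fit$history$model)
  expect_identical(as.integer(tab[["adversary"]]), 12L)
  expect_identical(as.integer(tab[["generator"]]), 4L)
  # cycle structure: 3 adversary rows then 1 generator row, repeated
  expect_identical(fit$history$model,
                   rep(c(rep("adversary", 3), "generator"), 4))
  expect_identical(fit$history$step, seq_len(16L))
})

test_that("zero iterations return the freshly initialized parameters", {
  spec <- tiny_spec()
  corpus <- build_corpus(1L, spec, seed = 1L)
  cfg <- desk_training_config(iterations = 0L, ratio = 0L, seed = 9L)
  fit <- train_alternating(corpus, tiny_gen_arch(), NULL, cfg)
  init <- adverseg:::with_seed(9L, {
    s <- sample.int(.Machine$integer.max - 1L, 1L)
    build_generator(tiny_gen_arch(), seed = s)
  })
  expect_identical(unclass(fit$generator), unclass(init))
  expect_identical(nrow(fit$history), 0L)
})

test_that("training runs are bit-identical under the same seed", {
  spec <- tiny_spec()
  corpus <- build_corpus(2L, spec, seed = 3L)
  cfg <- desk_training_config(iterations = 3L, ratio = 2L, batch_size = 2L,
                              seed = 21L)
  a <- train_alternating(corpus, tiny_gen_arch(dropout_rate = 0.5),
                         tiny_adv_arch(), cfg)
  b <- train_alternating(corpus, tiny_gen_arch(dropout_rate = 0.5),
                         tiny_adv_arch(), cfg)
  expect_identical(a$history, b$history)
  expect_identical(unclass(a$generator), unclass(b$generator))
  expect_identical(unclass(a$adversary), unclass(b$adversary))
})

test_that("ratio 0 trains a pure cross-entropy baseline with no adversary", {
  spec <- tiny_spec()
  corpus <- build_corpus(1L, spec, seed = 2L)
  cfg <- desk_training_config(iterations = 3L, ratio = 0L, batch_size = 2L,
                              seed = 2L)
  fit <- train_alternating(corpus, tiny_gen_arch(), NULL, cfg)
  expect_null(fit$adversary)
  expect_identical(unique(fit$history$model), "generator")
  expect_identical(nrow(fit$history), 3L)
})

test_that("the generator training loss decreases on a separable phantom task", {
  # noise-free phantom; compare loss after 100 baseline updates with the
  # loss at initialization, across 5 seeds (allowing 1 unlucky seed)
  spec <- tiny_spec(shape = c(16L, 16L, 3L), noise_sd = 0)
  wins <- 0L
  for (sd in 1:5) {
    corpus <- build_corpus(2L, spec, seed = sd)
    cfg <- desk_training_config(iterations = 100L, ratio = 0L,
                                batch_size = 4L, seed = sd * 7L)
    fit <- train_alternating(corpus, tiny_gen_arch(), NULL, cfg)
    losses <- fit$history$loss
    if (losses[100L] < losses[1L]) wins <- wins + 1L
  }
  expect_gte(wins, 4L)
})
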