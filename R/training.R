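#' Training configuration
#'
#' Hyperparameters of the alternating minimax loop. The defaults are the
#' published full-scale recipe: SGD with momentum 0.99 and weight decay
#' 1e-4, batch size 5, initial generator learning rate 1e-5 halved every
#' 5000 iterations, the adversary trained at a fixed 1e-5 on 3 batches per
#' generator batch, 100,000 generator iterations.
#' [desk_training_config()] is the scaled-down regime a single CPU core
#' finishes in minutes: it shortens the schedule roughly 200-fold and raises
#' both learning rates to 0.01 to compensate, since the published rate is
#' tied to the published 100,000-iteration budget.
#'
#' Parameter updates descend the mean-per-pixel, mean-per-sample gradient of
#' the objective, so step sizes do not grow with image or batch size; loss
#' *values* (in histories and the loss functions) remain the plain sums the
#' objective defines.
#'
#' @param total_generator_iterations Number of generator updates to run.
#' @param batch_size Samples per batch.
#' @param initial_lr Initial generator learning rate.
#' @param lr_halve_every Generator iterations between halvings.
#' @param momentum SGD momentum coefficient.
#' @param weight_decay Coupled L2 weight decay (added to the gradient).
#' @param ratio Adversary batches per generator batch; 0 disables
#'   adversarial training, giving the pure UG-net baseline trained on the
#'   multi-class cross-entropy alone.
#' @param adversary_lr Fixed adversary learning rate.
#' @param lambda_adv Scale on the generator's adversarial term.
#' @param seed Seed controlling batch sampling and dropout.
#' @return A `training_config` object.
#' @export
training_config <- function(total_generator_iterations = 100000L,
                            batch_size = 5L, initial_lr = 1e-5,
                            lr_halve_every = 5000L, momentum = 0.99,
                            weight_decay = 1e-4, ratio = 3L,
                            adversary_lr = 1e-5, lambda_adv = 1,
                            seed = 1L) {
  if (total_generator_iterations < 0L || batch_size < 1L ||
      initial_lr <= 0 || lr_halve_every < 1L || momentum < 0 ||
      weight_decay < 0 || ratio < 0L || adversary_lr <= 0)
    stopf("invalid training configuration")
  structure(list(total_generator_iterations = as.integer(total_generator_iterations),
                 batch_size = as.integer(batch_size),
                 initial_lr = initial_lr,
                 lr_halve_every = as.integer(lr_halve_every),
                 momentum = momentum, weight_decay = weight_decay,
                 ratio = as.integer(ratio), adversary_lr = adversary_lr,
                 lambda_adv = lambda_adv, seed = as.integer(seed)),
            class = "training_config")
}

#' @param iterations Generator iteration budget for the desk preset.
#' @param ... Other [training_config()] fields.
#' @rdname training_config
#' @export
desk_training_config <- function(iterations = 500L, ...) {
  args <- list(...)
  if (is.null(args$initial_lr)) args$initial_lr <- 0.01
  if (is.null(args$adversary_lr)) args$adversary_lr <- 0.01
  args$total_generator_iterations <- iterations
  do.call(training_config, args)
}

#' Learning-rate schedule
#'
#' The generator learning rate starts at `initial_lr` and is halved every
#' `lr_halve_every` iterations:
#' `initial_lr / 2^floor(iteration / lr_halve_every)`.
#'
#' @param iteration 0-based generator iteration count.
#' @param config A [training_config()].
#' @return The learning rate in effect at that iteration.
#' @examples
#' cfg <- training_config()
#' lr_at(0, cfg)      # 1e-5
#' lr_at(5000, cfg)   # 5e-6
#' @export
lr_at <- function(iteration, config) {
  if (any(iteration < 0)) stopf("iteration must be non-negative")
  config$initial_lr / 2^floor(iteration / config$lr_halve_every)
}

#' One SGD-momentum step with coupled weight decay
#'
#' Velocity form: `v <- momentum * v + (grad + weight_decay * param)`;
#' `param <- param - lr * v`. Weight decay is coupled (added to the
#' gradient before the momentum buffer).
#'
#' @param params Named list of numeric arrays.
#' @param grads Gradients, same structure as `params`.
#' @param velocity Momentum buffers, same structure (zeros on first call).
#' @param lr Learning rate.
#' @param momentum Momentum coefficient.
#' @param weight_decay L2 penalty coefficient.
#' @return List with updated `params` and `velocity`.
#' @export
sgd_momentum_step <- function(params, grads, velocity, lr, momentum,
                              weight_decay) {
  for (nm in names(params)) {
    gnm <- grads[[nm]]
    if (is.null(gnm) || length(gnm) != length(params[[nm]]))
      stopf("gradient for '%s' missing or mis-shaped", nm)
    if (!all(is.finite(gnm)))
      stopf("non-finite gradient in '%s'", nm)
    v <- momentum * velocity[[nm]] + (gnm + weight_decay * params[[nm]])
    velocity[[nm]] <- v
    params[[nm]] <- params[[nm]] - lr * v
  }
  list(params = params, velocity = velocity)
}

zero_like <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(a, b) {
  if (is.null(a)) return(b)
  for (nm in names(b)) a[[nm]] <- a[[nm]] + b[[nm]]
  a
}

# One generator update on a batch: mce gradient plus the adversarial term
# routed through the adversary's label-map input and the softmax. Update
# gradients are normalized per pixel and per sample so step sizes are
# independent of image size and batch size; the reported loss value stays
# the plain sum the objective defines.
generator_update_grads <- function(gen_params, adv_params, batch, lambda_adv) {
  M <- attr(gen_params, "arch")$num_classes
  grads <- NULL
  loss <- 0
  for (t in batch_tensors(batch, M)) {
    fw <- gen_forward(gen_params, t$x, training = TRUE, keep_cache = TRUE)
    p <- fw$prob
    loss <- loss + mce_loss(p, t$y)
    dlogits <- p - t$y
    if (!is.null(adv_params) && lambda_adv != 0) {
      af <- adv_forward(adv_params, t$x, p, keep_cache = TRUE)
      loss <- loss + lambda_adv * bce_loss(af$prob, 1)
      ab <- adv_backward(adv_params, af$cache,
                         dlogit = lambda_adv * (af$prob - 1),
                         need_label_grad = TRUE)
      dp <- ab$glabel
      s <- dp[, , 1L] * p[, , 1L]
      for (m in 2:M) s <- s + dp[, , m] * p[, , m]
      dlogits <- dlogits + p * (dp - as.vector(s))
    }
    grads <- add_grads(grads, gen_backward(gen_params, fw$cache, dlogits))
  }
  px <- nrow(batch[[1L]]$image) * ncol(batch[[1L]]$image)
  scale <- 1 / (length(batch) * px)
  grads <- lapply(grads, function(g) g * scale)
  list(grads = grads, loss = loss)
}

# One adversary update on a batch: expert pairs labelled 1, generated pairs
# (soft maps from the current generator, inference mode) labelled 0.
# Update gradients are normalized per sample (the loss terms are already
# O(1) per sample); reported loss stays the plain sum.
adversary_update_grads <- function(gen_params, adv_params, batch) {
  M <- attr(gen_params, "arch")$num_classes
  grads <- NULL
  loss <- 0
  for (t in batch_tensors(batch, M)) {
    p <- gen_forward(gen_params, t$x)$prob
    ar <- adv_forward(adv_params, t$x, t$y, keep_cache = TRUE)
    loss <- loss + bce_loss(ar$prob, 1)
    grads <- add_grads(grads,
                       adv_backward(adv_params, ar$cache,
                                    dlogit = ar$prob - 1)$grads)
    af <- adv_forward(adv_params, t$x, p, keep_cache = TRUE)
    loss <- loss + bce_loss(af$prob, 0)
    grads <- add_grads(grads,
                       adv_backward(adv_params, af$cache,
                                    dlogit = af$prob)$grads)
  }
  scale <- 1 / length(batch)
  grads <- lapply(grads, function(g) g * scale)
  list(grads = grads, loss = loss)
}

#' Alternating adversarial training
#'
#' Runs the minimax loop: each cycle performs `ratio` adversary updates on
#' fresh uniformly sampled batches (fixed adversary learning rate), then one
#' generator update (scheduled learning rate), until the generator has been
#' updated `total_generator_iterations` times. With `ratio = 0` no adversary
#' is built and the generator trains on the multi-class cross-entropy alone
#' — the pure UG-net baseline. Batches are drawn uniformly with replacement
#' from the training samples. Fully reproducible under `config$seed`.
#'
#' @param corpus A `seg_corpus` from [build_corpus()].
#' @param gen_arch A [generator_arch()].
#' @param adv_arch An [adversary_arch()] (ignored when `ratio = 0`).
#' @param config A [training_config()].
#' @param train_subjects Subject ids to train on (default: all).
#' @return List with `generator`, `adversary` (NULL for the baseline) and
#'   `history`, a data frame with one row per update: `step`, `model`,
#'   `loss`, `lr`.
#' @export
train_alternating <- function(corpus, gen_arch, adv_arch = NULL,
                              config = training_config(),
                              train_subjects = NULL) {
  stopifnot(inherits(corpus, "seg_corpus"), inherits(config, "training_config"))
  samples <- corpus$samples
  if (!is.null(train_subjects)) {
    samples <- Filter(function(s) s$subject_id %in% train_subjects, samples)
  }
  if (!length(samples)) stopf("no training samples")
  if (config$ratio > 0L && is.null(adv_arch))
    stopf("ratio > 0 requires an adversary architecture")

  n_updates <- config$total_generator_iterations * (1L + config$ratio)
  hist_step <- integer(n_updates)
  hist_model <- character(n_updates)
  hist_loss <- numeric(n_updates)
  hist_lr <- numeric(n_updates)
  row <- 0L

  with_seed(config$seed, {
    gen <- build_generator(gen_arch,
                           seed = sample.int(.Machine$integer.max - 1L, 1L))
    gen_vel <- zero_like(gen)
    adv <- NULL
    if (config$ratio > 0L) {
      adv <- build_adversary(adv_arch,
                             seed = sample.int(.Machine$integer.max - 1L, 1L))
      adv_vel <- zero_like(adv)
    }
    draw_batch <- function()
      samples[sample.int(length(samples), config$batch_size, replace = TRUE)]

    if (config$total_generator_iterations > 0L)
      for (it in seq_len(config$total_generator_iterations)) {
        if (config$ratio > 0L) {
          for (r in seq_len(config$ratio)) {
            upd <- adversary_update_grads(gen, adv, draw_batch())
            if (!is.finite(upd$loss))
              stopf("adversary loss non-finite at update %d", row + 1L)
            st <- sgd_momentum_step(adv, upd$grads, adv_vel,
                                    lr = config$adversary_lr,
                                    momentum = config$momentum,
                                    weight_decay = config$weight_decay)
            adv <- structure(st$params, arch = attr(adv, "arch"),
                             class = "adversary_params")
            adv_vel <- st$velocity
            row <- row + 1L
            hist_step[row] <- row; hist_model[row] <- "adversary"
            hist_loss[row] <- upd$loss; hist_lr[row] <- config$adversary_lr
          }
        }
        lr <- lr_at(it - 1L, config)
        upd <- generator_update_grads(gen, adv, draw_batch(),
                                      lambda_adv = config$lambda_adv)
        if (!is.finite(upd$loss))
          stopf("generator loss non-finite at update %d", row + 1L)
        st <- sgd_momentum_step(gen, upd$grads, gen_vel, lr = lr,
                                momentum = config$momentum,
                                weight_decay = config$weight_decay)
        gen <- structure(st$params, arch = attr(gen, "arch"),
                         class = "generator_params")
        gen_vel <- st$velocity
        row <- row + 1L
        hist_step[row] <- row; hist_model[row] <- "generator"
        hist_loss[row] <- upd$loss; hist_lr[row] <- lr
      }

    list(generator = gen, adversary = adv,
         history = data.frame(step = hist_step[seq_len(row)],
                              model = hist_model[seq_len(row)],
                              loss = hist_loss[seq_len(row)],
                              lr = hist_lr[seq_len(row)]))
  })
}
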