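#' UG-net generator architecture
#'
#' A U-net variant with a single 3x3 zero-padded convolution per block
#' (rather than the original two), so spatial size is preserved through
#' every convolution and the parameter count stays modest. The encoder
#' halves resolution with 2x2 max pooling while doubling channels; the
#' decoder mirrors it with nearest-neighbour upsampling + convolution,
#' concatenating the matching encoder feature map (skip connection) before
#' each decoder convolution, with dropout on the decoder (upsampling)
#' blocks. The head is one 3x3 convolution to `num_classes` channels
#' followed by a per-pixel softmax, yielding a class probability map; a
#' `single_channel` head mode instead returns the argmax label image, for
#' export and visualization only (the multi-class cross-entropy loss needs
#' the M-channel map).
#'
#' @param depth Number of pooling levels (>= 1).
#' @param base_channels Channels at the first encoder level; doubles per
#'   level. `generator_arch()` gives a full-scale default (depth 4, 64
#'   channels); [desk_generator_arch()] a small CPU-scale preset.
#' @param num_classes Number of output classes M.
#' @param dropout_rate Dropout fraction on decoder blocks (training only).
#' @param head_mode `"multi_channel_softmax"` (default) or
#'   `"single_channel"`.
#' @return A `generator_arch` object.
#' @export
generator_arch <- function(depth = 4L, base_channels = 64L, num_classes = 10L,
                           dropout_rate = 0.5,
                           head_mode = c("multi_channel_softmax",
                                         "single_channel")) {
  head_mode <- match.arg(head_mode)
  if (depth < 1L || base_channels < 1L || num_classes < 2L)
    stopf("invalid generator architecture")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stopf("dropout_rate must be in [0, 1)")
  structure(list(depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 num_classes = as.integer(num_classes),
                 kernel_size = 3L, dropout_rate = dropout_rate,
                 head_mode = head_mode),
            class = "generator_arch")
}

#' @param ... Passed on to [generator_arch()].
#' @rdname generator_arch
#' @export
desk_generator_arch <- function(num_classes = 10L, ...) {
  generator_arch(depth = 3L, base_channels = 8L, num_classes = num_classes,
                 ...)
}

# Layer plan: names, input and output channel counts, in forward order.
gen_layer_plan <- function(arch) {
  d <- arch$depth; b <- arch$base_channels
  plan <- list()
  for (l in seq_len(d)) {
    cin <- if (l == 1L) 1L else b * 2L^(l - 2L)
    plan[[paste0("enc", l)]] <- c(cin = cin, cout = b * 2L^(l - 1L))
  }
  plan[["bott"]] <- c(cin = b * 2L^(d - 1L), cout = b * 2L^d)
  for (l in rev(seq_len(d))) {
    up <- if (l == d) b * 2L^d else b * 2L^l
    plan[[paste0("dec", l)]] <- c(cin = up + b * 2L^(l - 1L),
                                  cout = b * 2L^(l - 1L))
  }
  plan[["head"]] <- c(cin = b, cout = arch$num_classes)
  plan
}

init_conv <- function(cin, cout) {
  # He-normal initialization for rectified-linear layers
  list(W = matrix(stats::rnorm(cout * cin * 9L, 0, sqrt(2 / (cin * 9L))),
                  nrow = cout, ncol = cin * 9L),
       b = rep(0, cout))
}

#' Build (initialize) generator parameters
#'
#' Returns the trainable weight container for a [generator_arch()], with
#' He-normal weights and zero biases, deterministic under `seed`.
#'
#' @param arch A [generator_arch()].
#' @param seed Integer seed for the initialization.
#' @return A `generator_params` object: a flat named list of weight
#'   matrices/bias vectors with the architecture attached as an attribute.
#' @export
build_generator <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "generator_arch"))
  plan <- gen_layer_plan(arch)
  params <- with_seed(seed, {
    p <- list()
    for (nm in names(plan)) {
      lay <- init_conv(plan[[nm]]["cin"], plan[[nm]]["cout"])
      p[[paste0(nm, "_W")]] <- lay$W
      p[[paste0(nm, "_b")]] <- lay$b
    }
    p
  })
  structure(params, arch = arch, class = "generator_params")
}

#' @export
print.generator_params <- function(x, ...) {
  arch <- attr(x, "arch")
  np <- sum(vapply(x, length, 0L))
  cat(sprintf("<generator_params> depth %d, base %d, M=%d, %d parameters\n",
              arch$depth, arch$base_channels, arch$num_classes, np))
  invisible(x)
}

check_gen_input <- function(arch, image) {
  H <- nrow(image); W <- ncol(image)
  div <- 2L^arch$depth
  if (H %% div != 0L || W %% div != 0L)
    stopf(paste0("input %dx%d not divisible by 2^depth = %d; ",
                 "pad or crop the slice to a multiple of %d"),
          H, W, div, div)
}

# Forward pass. `x01` is the H x W image already scaled to [0, 1].
# In training mode dropout draws come from the current R RNG stream, so a
# seeded caller gets reproducible stochasticity.
gen_forward <- function(params, x01, training = FALSE, keep_cache = FALSE) {
  arch <- attr(params, "arch")
  d <- arch$depth
  cache <- list(enc_in = vector("list", d), enc_post = vector("list", d),
                pool_idx = vector("list", d), dec_in = vector("list", d),
                dec_post = vector("list", d), drop_mask = vector("list", d))
  a <- array(x01, dim = c(nrow(x01), ncol(x01), 1L))
  skips <- vector("list", d)
  for (l in seq_len(d)) {
    if (keep_cache) cache$enc_in[[l]] <- a
    z <- .conv_fwd(a, params[[paste0("enc", l, "_W")]],
                   params[[paste0("enc", l, "_b")]])
    r <- .relu_cube(z)
    skips[[l]] <- r
    if (keep_cache) cache$enc_post[[l]] <- r
    pl <- .pool_fwd(r)
    if (keep_cache) cache$pool_idx[[l]] <- pl$idx
    a <- pl$out
  }
  if (keep_cache) cache$bott_in <- a
  z <- .conv_fwd(a, params$bott_W, params$bott_b)
  a <- .relu_cube(z)
  if (keep_cache) cache$bott_post <- a
  for (l in rev(seq_len(d))) {
    u <- .upsample_fwd(a)
    cc <- array(c(u, skips[[l]]),
                dim = c(dim(u)[1L], dim(u)[2L], dim(u)[3L] + dim(skips[[l]])[3L]))
    if (keep_cache) cache$dec_in[[l]] <- cc
    z <- .conv_fwd(cc, params[[paste0("dec", l, "_W")]],
                   params[[paste0("dec", l, "_b")]])
    r <- .relu_cube(z)
    if (training && arch$dropout_rate > 0) {
      mask <- (stats::runif(length(r)) >= arch$dropout_rate) /
        (1 - arch$dropout_rate)
      dim(mask) <- dim(r)
      r <- r * mask
      if (keep_cache) cache$drop_mask[[l]] <- mask
    }
    if (keep_cache) cache$dec_post[[l]] <- r
    a <- r
  }
  if (keep_cache) cache$head_in <- a
  logits <- .conv_fwd(a, params$head_W, params$head_b)
  prob <- softmax_channels(logits)
  list(prob = prob, logits = logits, cache = cache)
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
gen_backward <- function(params, cache, dlogits) {
  arch <- attr(params, "arch")
  d <- arch$depth
  g <- list()
  bw <- .conv_bwd(cache$head_in, params$head_W, dlogits)
  g$head_W <- bw$gW; g$head_b <- bw$gb
  da <- bw$gx
  dskips <- vector("list", d)
  for (l in seq_len(d)) {           # decoder ran depth..1; reverse is 1..depth
    if (!is.null(cache$drop_mask[[l]])) da <- da * cache$drop_mask[[l]]
    da <- .relu_bwd(da, cache$dec_post[[l]])
    bw <- .conv_bwd(cache$dec_in[[l]], params[[paste0("dec", l, "_W")]], da)
    g[[paste0("dec", l, "_W")]] <- bw$gW
    g[[paste0("dec", l, "_b")]] <- bw$gb
    cu <- dim(bw$gx)[3L] - dim(cache$enc_post[[l]])[3L]
    dskips[[l]] <- bw$gx[, , (cu + 1L):dim(bw$gx)[3L], drop = FALSE]
    da <- .upsample_bwd(bw$gx[, , seq_len(cu), drop = FALSE])
  }
  da <- .relu_bwd(da, cache$bott_post)
  bw <- .conv_bwd(cache$bott_in, params$bott_W, da)
  g$bott_W <- bw$gW; g$bott_b <- bw$gb
  da <- bw$gx
  for (l in rev(seq_len(d))) {
    hp <- dim(cache$enc_post[[l]])[1L]; wp <- dim(cache$enc_post[[l]])[2L]
    da <- .pool_bwd(da, cache$pool_idx[[l]], hp, wp) + dskips[[l]]
    da <- .relu_bwd(da, cache$enc_post[[l]])
    bw <- .conv_bwd(cache$enc_in[[l]], params[[paste0("enc", l, "_W")]], da)
    g[[paste0("enc", l, "_W")]] <- bw$gW
    g[[paste0("enc", l, "_b")]] <- bw$gb
    da <- bw$gx
  }
  g[names(params)]
}

#' Generator forward pass
#'
#' Maps one slice image to its per-pixel class probability map (or, in
#' `single_channel` head mode, the argmax label image). Inference mode:
#' dropout is disabled, so repeated calls are bit-identical.
#'
#' @param params [build_generator()] output.
#' @param image H x W numeric matrix scaled to `[0, 1]`; H and W must be
#'   divisible by `2^depth`.
#' @return H x W x M probability array (each pixel's channel vector sums to
#'   1), or an H x W integer label matrix in `single_channel` mode.
#' @export
generator_forward <- function(params, image) {
  stopifnot(inherits(params, "generator_params"))
  arch <- attr(params, "arch")
  image <- as.matrix(image)
  check_gen_input(arch, image)
  out <- gen_forward(params, image, training = FALSE)
  if (arch$head_mode == "single_channel") argmax_channels(out$prob)
  else out$prob
}
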