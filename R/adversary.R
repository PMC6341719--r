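#' Adversary (discriminator) architecture
#'
#' The adversarial model scores an (image, label map) pair with the
#' probability that the label map is an expert annotation rather than a
#' generated one. The image and the label map are first processed by two
#' separate single-convolution branches with the *same* number of channels
#' each — so neither signal dominates — and concatenated; by default 32 + 32
#' = 64 channels. A trunk of 3x3 convolution + rectifier + 2x2 max-pool
#' stages follows, then global average pooling and a dense layer to a single
#' sigmoid probability. The global pooling gives the final score a field of
#' view spanning the whole image by construction.
#'
#' @param branch_channels Channels per input branch (default 32, giving the
#'   64-channel concatenated representation).
#' @param trunk_channels Output channels of the successive conv+pool stages.
#' @param num_classes Channels expected on the label-map input (M).
#' @return An `adversary_arch` object.
#' @export
adversary_arch <- function(branch_channels = 32L,
                           trunk_channels = c(64L, 128L, 256L),
                           num_classes = 10L) {
  if (branch_channels < 1L || length(trunk_channels) < 1L)
    stopf("invalid adversary architecture")
  structure(list(branch_channels = as.integer(branch_channels),
                 trunk_channels = as.integer(trunk_channels),
                 num_classes = as.integer(num_classes)),
            class = "adversary_arch")
}

#' @param ... Passed on to [adversary_arch()].
#' @rdname adversary_arch
#' @export
desk_adversary_arch <- function(num_classes = 10L, ...) {
  adversary_arch(branch_channels = 8L, trunk_channels = c(16L, 32L, 64L),
                 num_classes = num_classes, ...)
}

#' Build (initialize) adversary parameters
#'
#' @param arch An [adversary_arch()].
#' @param seed Integer seed.
#' @return An `adversary_params` object (flat named weight list with the
#'   architecture attached).
#' @export
build_adversary <- function(arch, seed = 1L) {
  stopifnot(inherits(arch, "adversary_arch"))
  with_seed(seed, {
    p <- list()
    br <- init_conv(1L, arch$branch_channels)
    p$img_W <- br$W; p$img_b <- br$b
    br <- init_conv(arch$num_classes, arch$branch_channels)
    p$lab_W <- br$W; p$lab_b <- br$b
    cin <- 2L * arch$branch_channels
    for (s in seq_along(arch$trunk_channels)) {
      lay <- init_conv(cin, arch$trunk_channels[s])
      p[[paste0("trunk", s, "_W")]] <- lay$W
      p[[paste0("trunk", s, "_b")]] <- lay$b
      cin <- arch$trunk_channels[s]
    }
    ch <- arch$trunk_channels[length(arch$trunk_channels)]
    p$dense_w <- stats::rnorm(ch, 0, sqrt(1 / ch))
    p$dense_b <- 0
    structure(p, arch = arch, class = "adversary_params")
  })
}

#' @export
print.adversary_params <- function(x, ...) {
  arch <- attr(x, "arch")
  np <- sum(vapply(x, length, 0L))
  cat(sprintf("<adversary_params> branches %d+%d, trunk %s, %d parameters\n",
              arch$branch_channels, arch$branch_channels,
              paste(arch$trunk_channels, collapse = "-"), np))
  invisible(x)
}

adv_forward <- function(params, image01, label_map, keep_cache = FALSE) {
  arch <- attr(params, "arch")
  image01 <- as.matrix(image01)
  if (!identical(dim(image01), dim(label_map)[1:2]))
    stopf("image and label map spatial shapes differ")
  if (dim(label_map)[3L] != arch$num_classes)
    stopf("label map has %d channels, adversary expects M = %d",
          dim(label_map)[3L], arch$num_classes)
  ns <- length(arch$trunk_channels)
  div <- 2L^ns
  if (nrow(image01) %% div != 0L || ncol(image01) %% div != 0L)
    stopf("input %dx%d not divisible by 2^stages = %d",
          nrow(image01), ncol(image01), div)
  cache <- list(stage_in = vector("list", ns), stage_post = vector("list", ns),
                pool_idx = vector("list", ns), pre_dim = vector("list", ns))
  xi <- array(image01, dim = c(nrow(image01), ncol(image01), 1L))
  zi <- .conv_fwd(xi, params$img_W, params$img_b)
  ri <- .relu_cube(zi)
  zl <- .conv_fwd(label_map, params$lab_W, params$lab_b)
  rl <- .relu_cube(zl)
  concat <- array(c(ri, rl),
                  dim = c(dim(ri)[1L], dim(ri)[2L], dim(ri)[3L] + dim(rl)[3L]))
  if (keep_cache) {
    cache$img_in <- xi; cache$img_post <- ri
    cache$lab_in <- label_map; cache$lab_post <- rl
  }
  cache$concat_channels <- dim(concat)[3L]
  a <- concat
  for (s in seq_len(ns)) {
    if (keep_cache) cache$stage_in[[s]] <- a
    z <- .conv_fwd(a, params[[paste0("trunk", s, "_W")]],
                   params[[paste0("trunk", s, "_b")]])
    r <- .relu_cube(z)
    if (keep_cache) { cache$stage_post[[s]] <- r
                      cache$pre_dim[[s]] <- dim(r)[1:2] }
    pl <- .pool_fwd(r)
    if (keep_cache) cache$pool_idx[[s]] <- pl$idx
    a <- pl$out
  }
  feat <- apply(a, 3L, mean)          # global average pooling
  if (keep_cache) { cache$gap_in_dim <- dim(a); cache$feat <- feat }
  logit <- sum(params$dense_w * feat) + params$dense_b
  prob <- 1 / (1 + exp(-logit))
  list(prob = prob, logit = logit, cache = cache)
}

# Backward from d(loss)/d(logit); returns parameter gradients and, when
# `need_label_grad`, the gradient with respect to the label-map input (the
# differentiable path the generator's adversarial term needs).
adv_backward <- function(params, cache, dlogit, need_label_grad = FALSE) {
  arch <- attr(params, "arch")
  ns <- length(arch$trunk_channels)
  g <- list()
  g$dense_w <- dlogit * cache$feat
  g$dense_b <- dlogit
  gdim <- cache$gap_in_dim
  npx <- gdim[1L] * gdim[2L]
  da <- array(rep(dlogit * params$dense_w / npx, each = npx), dim = gdim)
  for (s in rev(seq_len(ns))) {
    da <- .pool_bwd(da, cache$pool_idx[[s]], cache$pre_dim[[s]][1L],
                    cache$pre_dim[[s]][2L])
    da <- .relu_bwd(da, cache$stage_post[[s]])
    bw <- .conv_bwd(cache$stage_in[[s]], params[[paste0("trunk", s, "_W")]], da)
    g[[paste0("trunk", s, "_W")]] <- bw$gW
    g[[paste0("trunk", s, "_b")]] <- bw$gb
    da <- bw$gx
  }
  bc <- arch$branch_channels
  di <- .relu_bwd(da[, , seq_len(bc), drop = FALSE], cache$img_post)
  dl <- .relu_bwd(da[, , bc + seq_len(bc), drop = FALSE], cache$lab_post)
  bw <- .conv_bwd(cache$img_in, params$img_W, di)
  g$img_W <- bw$gW; g$img_b <- bw$gb
  bw <- .conv_bwd(cache$lab_in, params$lab_W, dl)
  g$lab_W <- bw$gW; g$lab_b <- bw$gb
  out <- list(grads = g[names(params)])
  if (need_label_grad) out$glabel <- bw$gx
  out
}

#' Adversary forward pass
#'
#' Scores an (image, label map) pair. Expert annotations should be fed
#' one-hot ([one_hot_encode()]); generated segmentations are fed as the
#' soft probability map, which keeps the generator's adversarial gradient
#' path intact during training.
#'
#' @param params [build_adversary()] output.
#' @param image H x W numeric matrix scaled to `[0, 1]`.
#' @param label_map H x W x M array, each pixel on the probability simplex.
#' @return A single probability strictly inside (0, 1).
#' @export
adversary_forward <- function(params, image, label_map) {
  stopifnot(inherits(params, "adversary_params"))
  adv_forward(params, image, label_map)$prob
}
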