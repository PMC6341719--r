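# Shared fixtures: tiny architectures, corpora and literal-formula oracles.
# Everything is generated in code under fixed seeds; nothing is stored.

tiny_scheme <- function() subfield_scheme(c("background", "large", "small"))

tiny_spec <- function(shape = c(16L, 16L, 3L), noise_sd = 5, seed = 1L) {
  phantom_spec(shape = shape, noise_sd = noise_sd, seed = seed,
               scheme = tiny_scheme())
}

tiny_gen_arch <- function(M = 3L, depth = 2L, dropout_rate = 0)
  generator_arch(depth = depth, base_channels = 4L, num_classes = M,
                 dropout_rate = dropout_rate)

tiny_adv_arch <- function(M = 3L)
  adversary_arch(branch_channels = 4L, trunk_channels = c(4L, 8L),
                 num_classes = M)

tiny_batch <- function(n = 2L, H = 16L, W = 16L, M = 3L, seed = 99L) {
  adverseg:::with_seed(seed, {
    lapply(seq_len(n), function(i)
      slice_sample(matrix(runif(H * W, 0, 255), H, W),
                   matrix(sample(0:(M - 1L), H * W, replace = TRUE), H, W),
                   subject_id = sprintf("s%02d", i), slice_index = 1L))
  })
}

# An adversary whose every weight is zero scores 0.5 on any input
# (sigmoid(0)); handy for closed-form loss checks.
half_adversary <- function(M = 3L) {
  ap <- build_adversary(tiny_adv_arch(M), seed = 1L)
  zeroed <- lapply(unclass(ap), function(p) p * 0)
  structure(zeroed, arch = attr(ap, "arch"), class = "adversary_params")
}

# ---- literal-formula oracles (independent of the package's vectorized
# implementations; deliberately written as plain double loops) ----

oracle_mce <- function(prob, target, eps = 1e-12) {
  total <- 0
  for (i in seq_len(dim(prob)[1L]))
    for (j in seq_len(dim(prob)[2L]))
      for (m in seq_len(dim(prob)[3L]))
        total <- total - target[i, j, m] * log(max(prob[i, j, m], eps))
  total
}

oracle_bce <- function(pred, target, eps = 1e-12) {
  p <- min(max(pred, eps), 1 - eps)
  -(target * log(p) + (1 - target) * log(1 - p))
}

oracle_dsc <- function(a, b) {
  inter <- 0L; na <- 0L; nb <- 0L
  for (k in seq_along(a)) {
    if (a[k] && b[k]) inter <- inter + 1L
    if (a[k]) na <- na + 1L
    if (b[k]) nb <- nb + 1L
  }
  if (na + nb == 0L) return(1.0)
  2 * inter / (na + nb)
}

# Random probability map on the simplex, plus a matching one-hot target.
random_prob_target <- function(H, W, M) {
  z <- array(rexp(H * W * M), dim = c(H, W, M))
  s <- z[, , 1L]
  if (M > 1L) for (m in 2:M) s <- s + z[, , m]
  prob <- z / as.vector(s)
  target <- one_hot_encode(matrix(sample(0:(M - 1L), H * W, TRUE), H, W), M)
  list(prob = prob, target = target)
}
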