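# Internal helpers shared across modules.

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards so library calls never perturb user code.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of child seeds from a parent seed (kept below 2^31).
derive_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

stopf <- function(...) stop(sprintf(...), call. = FALSE)
warnf <- function(...) warning(sprintf(...), call. = FALSE)

as_cube <- function(x) {
  if (is.matrix(x)) array(x, dim = c(dim(x), 1L)) else x
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

# Per-pixel softmax over the channel (third) dimension of an H x W x M array.
softmax_channels <- function(z) {
  M <- dim(z)[3L]
  mx <- z[, , 1L]
  if (M > 1L) for (m in 2:M) mx <- pmax(mx, z[, , m])
  e <- exp(z - as.vector(mx))
  s <- e[, , 1L]
  if (M > 1L) for (m in 2:M) s <- s + e[, , m]
  e / as.vector(s)
}

# Lowest-index argmax over channels; strict `>` keeps the lower class index
# on exact ties.
argmax_channels <- function(p) {
  M <- dim(p)[3L]
  best <- matrix(1L, nrow = dim(p)[1L], ncol = dim(p)[2L])
  bestv <- p[, , 1L]
  if (M > 1L) for (m in 2:M) {
    sel <- p[, , m] > bestv
    best[sel] <- m
    bestv[sel] <- p[, , m][sel]
  }
  best - 1L  # 0-based class indices
}
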