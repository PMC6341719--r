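# The hybrid objective: a multi-class cross-entropy term driving pixel-wise
# accuracy plus an adversarial binary cross-entropy term penalizing label
# maps the adversary can tell apart from expert annotations. Probabilities
# are clamped to [1e-12, 1] inside logarithms, where the raw formulas are
# undefined at exact 0/1.

LOG_EPS <- 1e-12

#' Multi-class cross-entropy loss
#'
#' `-sum_i sum_m y_im * ln(p_im)` summed over all pixels i and classes m of
#' one slice: zero iff the probability map puts mass 1 on the true class at
#' every pixel.
#'
#' @param prob_map H x W x M class probability array.
#' @param target H x W x M one-hot target ([one_hot_encode()]).
#' @return Non-negative scalar.
#' @export
mce_loss <- function(prob_map, target) {
  if (!identical(dim(prob_map), dim(target)))
    stopf("probability map and target shapes differ")
  -sum(target * log(pmax(prob_map, LOG_EPS)))
}

#' Binary cross-entropy loss
#'
#' `-(a * ln(p) + (1 - a) * ln(1 - p))` for a predicted probability `p` and
#' a binary target `a`.
#'
#' @param pred Predicted probability in `[0, 1]` (clamped internally).
#' @param target 0 or 1.
#' @return Non-negative scalar.
#' @export
bce_loss <- function(pred, target) {
  if (!(length(target) == 1L && target %in% c(0, 1)))
    stopf("binary cross-entropy target must be 0 or 1")
  p <- min(max(pred, LOG_EPS), 1 - LOG_EPS)
  -(target * log(p) + (1 - target) * log(1 - p))
}

# A batch is a list of slice_sample objects. Images enter the networks
# scaled to [0, 1]; labels are one-hot encoded against M.
batch_tensors <- function(batch, M) {
  lapply(batch, function(s)
    list(x = s$image / 255, y = one_hot_encode(s$label, M)))
}

#' Hybrid adversarial segmentation objective
#'
#' Evaluates, for a batch of (image, label) pairs, the combined loss
#' `sum_n [ mce(g(x_n), y_n) - ( bce(a(x_n, y_n), 1) +
#' bce(a(x_n, g(x_n)), 0) ) ]`: the segmentation cross-entropy minus the
#' adversary's discrimination loss. This is the quantity the minimax game
#' descends/ascends; the per-model training losses used for updates are
#' [generator_training_loss()] and [adversary_training_loss()].
#'
#' @param gen_params Generator parameters.
#' @param adv_params Adversary parameters.
#' @param batch Non-empty list of [slice_sample()]s.
#' @return Scalar objective value (diagnostic; not used for updates).
#' @export
combined_objective <- function(gen_params, adv_params, batch) {
  if (!length(batch)) stopf("empty batch")
  M <- attr(gen_params, "arch")$num_classes
  total <- 0
  for (t in batch_tensors(batch, M)) {
    p <- gen_forward(gen_params, t$x)$prob
    a_real <- adv_forward(adv_params, t$x, t$y)$prob
    a_fake <- adv_forward(adv_params, t$x, p)$prob
    total <- total + mce_loss(p, t$y) -
      (bce_loss(a_real, 1) + bce_loss(a_fake, 0))
  }
  total
}

#' Generator-side training loss
#'
#' The terms of the hybrid objective relevant to the generator, with the
#' non-saturating substitution: instead of minimizing
#' `-bce(a(x, g(x)), 0)`, the generator minimizes
#' `+bce(a(x, g(x)), 1)` — maximizing the probability that the adversary
#' takes its output for an expert annotation — which yields stronger
#' gradients early in training. Adversary parameters are treated as
#' constants (no gradient flows into them).
#'
#' @inheritParams combined_objective
#' @param lambda_adv Scale on the adversarial term (1 = the plain hybrid
#'   objective).
#' @return Scalar: `sum_n [ mce(g(x_n), y_n) + lambda *
#'   bce(a(x_n, g(x_n)), 1) ]`.
#' @export
generator_training_loss <- function(gen_params, adv_params, batch,
                                    lambda_adv = 1) {
  if (!length(batch)) stopf("empty batch")
  M <- attr(gen_params, "arch")$num_classes
  total <- 0
  for (t in batch_tensors(batch, M)) {
    p <- gen_forward(gen_params, t$x)$prob
    a_fake <- adv_forward(adv_params, t$x, p)$prob
    total <- total + mce_loss(p, t$y) + lambda_adv * bce_loss(a_fake, 1)
  }
  total
}

#' Adversary-side training loss
#'
#' The binary classification loss `sum_n [ bce(a(x_n, y_n), 1) +
#' bce(a(x_n, g(x_n)), 0) ]`: label expert annotations 1, generated maps 0.
#' Generator parameters are treated as constants; generated maps are
#' produced fresh from the current generator in inference mode.
#'
#' @inheritParams combined_objective
#' @return Non-negative scalar.
#' @export
adversary_training_loss <- function(gen_params, adv_params, batch) {
  if (!length(batch)) stopf("empty batch")
  M <- attr(gen_params, "arch")$num_classes
  total <- 0
  for (t in batch_tensors(batch, M)) {
    p <- gen_forward(gen_params, t$x)$prob
    a_real <- adv_forward(adv_params, t$x, t$y)$prob
    a_fake <- adv_forward(adv_params, t$x, p)$prob
    total <- total + bce_loss(a_real, 1) + bce_loss(a_fake, 0)
  }
  total
}
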