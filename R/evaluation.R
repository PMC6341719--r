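#' Dice similarity coefficient
#'
#' `DSC(S1, S2) = 2 |S1 intersect S2| / (|S1| + |S2|)` between two binary
#' masks of equal shape. Symmetric, bounded in `[0, 1]`, 1 for identical
#' non-empty masks. When both masks are empty the coefficient is undefined
#' (0/0); the package returns 1.0 by convention — the prediction is
#' vacuously perfect — and [volume_dsc()] flags such classes.
#'
#' @param s1,s2 Logical arrays (any shape, shapes must match). `s1` is
#'   conventionally the generated segmentation, `s2` the expert one.
#' @return DSC in `[0, 1]`.
#' @examples
#' dsc(matrix(c(TRUE, TRUE, FALSE), 1), matrix(c(TRUE, FALSE, FALSE), 1))
#' @export
dsc <- function(s1, s2) {
  if (!identical(dim(s1), dim(s2)))
    stopf("mask shapes differ")
  n1 <- sum(s1); n2 <- sum(s2)
  if (n1 + n2 == 0) return(1.0)
  2 * sum(s1 & s2) / (n1 + n2)
}

#' Volume-level multi-class Dice report
#'
#' Segmentation runs on 2D slices, but accuracy is scored at the volume
#' level: predicted slices are stacked into a 3D label volume, and for each
#' foreground class the 3D binary masks of prediction and truth are
#' compared with [dsc()]. `overall` is the DSC of the whole-structure mask
#' (union of all foreground classes); a size-weighted mean of the per-class
#' values is also reported as `weighted_mean` for comparison.
#'
#' @param predicted_slices List of H x W integer label matrices, one per
#'   depth index.
#' @param truth The reference [label_volume()].
#' @param scheme Scheme naming the classes (default: the truth's scheme).
#' @return A `dsc_report`: list with `per_class` (named numeric),
#'   `overall`, `weighted_mean`, and `both_empty` (named logical flags).
#' @export
volume_dsc <- function(predicted_slices, truth, scheme = truth$scheme) {
  stopifnot(inherits(truth, "label_volume"))
  D <- dim(truth$labels)[3L]
  if (length(predicted_slices) != D)
    stopf("got %d predicted slices for a depth-%d volume",
          length(predicted_slices), D)
  pred <- array(0L, dim = dim(truth$labels))
  for (k in seq_len(D)) {
    if (!identical(dim(predicted_slices[[k]]), dim(truth$labels)[1:2]))
      stopf("slice %d shape mismatch", k)
    pred[, , k] <- predicted_slices[[k]]
  }
  fg <- foreground_classes(scheme)
  per_class <- numeric(length(fg)); names(per_class) <- fg
  both_empty <- logical(length(fg)); names(both_empty) <- fg
  sizes <- numeric(length(fg))
  for (m in seq_along(fg)) {
    pm <- pred == m
    tm <- truth$labels == m
    per_class[m] <- dsc(pm, tm)
    both_empty[m] <- !any(pm) && !any(tm)
    sizes[m] <- sum(tm)
  }
  overall <- dsc(pred != 0L, truth$labels != 0L)
  weighted <- if (sum(sizes) > 0) sum(per_class * sizes) / sum(sizes) else NA_real_
  structure(list(per_class = per_class, overall = overall,
                 weighted_mean = weighted, both_empty = both_empty),
            class = "dsc_report")
}

#' @export
print.dsc_report <- function(x, ...) {
  cat("<dsc_report>\n")
  for (nm in names(x$per_class))
    cat(sprintf("  %-12s %.4f%s\n", nm, x$per_class[[nm]],
                if (x$both_empty[[nm]]) " (both empty)" else ""))
  cat(sprintf("  %-12s %.4f\n", "overall", x$overall))
  if (!is.null(x$fold_mean)) {
    cat(sprintf("  fold overall mean %.4f sd %.4f\n",
                mean(x$fold_mean), stats::sd(x$fold_mean)))
  }
  invisible(x)
}

#' Segment a volume slice-wise
#'
#' Applies the generator to every depth slice of a normalized ROI volume
#' and takes the per-pixel argmax of the class probability map; exact ties
#' resolve to the lower class index, so prediction is deterministic.
#'
#' @param gen_params Trained [build_generator()] parameters.
#' @param intensity An [intensity_volume()] on the `[0, 255]` scale.
#' @return List of H x W integer label matrices, one per depth slice.
#' @export
predict_volume <- function(gen_params, intensity) {
  stopifnot(inherits(intensity, "intensity_volume"))
  D <- dim(intensity$values)[3L]
  lapply(seq_len(D), function(k) {
    p <- gen_forward(gen_params, intensity$values[, , k] / 255)$prob
    argmax_channels(p)
  })
}

#' Subject-level cross-validation folds
#'
#' Randomly partitions subject ids into `k` folds whose sizes differ by at
#' most one. Splitting at the subject level (and assigning augmented
#' samples to their base subject's fold) is what prevents augmented copies
#' of a validation subject from leaking into training.
#'
#' @param subject_ids Character vector of subject ids.
#' @param k Number of folds (`k <= length(subject_ids)`).
#' @param seed Seed for the shuffle.
#' @return A `fold_split`: list with `k` and `assignment` (named integer
#'   vector, subject id -> fold).
#' @export
make_folds <- function(subject_ids, k, seed = 1L) {
  subject_ids <- unique(as.character(subject_ids))
  if (k > length(subject_ids))
    stopf("k = %d exceeds the %d subjects", k, length(subject_ids))
  if (k < 2L) stopf("need at least 2 folds")
  with_seed(seed, {
    shuffled <- sample(subject_ids)
    assignment <- rep(seq_len(k), length.out = length(shuffled))
    names(assignment) <- shuffled
    structure(list(k = as.integer(k), assignment = assignment),
              class = "fold_split")
  })
}

#' Cross-validated segmentation accuracy
#'
#' For each fold: trains on the remaining folds' samples (base and
#' augmented), segments each held-out subject's volume slice-wise, and
#' scores it with [volume_dsc()]. Per-class and overall values are
#' averaged across held-out subjects within a fold, then mean and standard
#' deviation are reported across folds.
#'
#' @param corpus A `seg_corpus`.
#' @param k Fold count.
#' @param gen_arch,adv_arch Network architectures.
#' @param config A [training_config()].
#' @param seed Seed for the fold split.
#' @param trainer Training function `(corpus, gen_arch, adv_arch, config,
#'   train_subjects) -> list(generator = ...)`; defaults to
#'   [train_alternating()]. Injectable so evaluation logic can be tested
#'   with an oracle generator.
#' @param predictor Prediction function `(generator, intensity_volume) ->
#'   list of label matrices`; defaults to [predict_volume()].
#' @return A `dsc_report` with fold statistics: `per_class` / `overall` are
#'   means across folds; `per_class_sd`, `overall_sd` and `fold_mean` (the
#'   per-fold overall values) accompany them.
#' @export
crossvalidate <- function(corpus, k, gen_arch, adv_arch = NULL,
                          config = training_config(), seed = 1L,
                          trainer = train_alternating,
                          predictor = predict_volume) {
  stopifnot(inherits(corpus, "seg_corpus"))
  subjects <- corpus_subjects(corpus)
  folds <- make_folds(subjects, k, seed = seed)
  fg <- foreground_classes(corpus$scheme)
  fold_class <- matrix(NA_real_, nrow = k, ncol = length(fg),
                       dimnames = list(NULL, fg))
  fold_overall <- numeric(k)
  for (f in seq_len(k)) {
    val_subjects <- names(folds$assignment)[folds$assignment == f]
    if (!length(val_subjects)) stopf("fold %d has no validation subjects", f)
    train_subjects <- setdiff(subjects, val_subjects)
    fit <- trainer(corpus, gen_arch, adv_arch, config,
                   train_subjects = train_subjects)
    reports <- lapply(val_subjects, function(sid) {
      vols <- corpus$volumes[[sid]]
      pred <- predictor(fit$generator, vols$intensity)
      volume_dsc(pred, vols$label, scheme = corpus$scheme)
    })
    fold_class[f, ] <- colMeans(do.call(rbind,
                                        lapply(reports, `[[`, "per_class")))
    fold_overall[f] <- mean(vapply(reports, `[[`, 0, "overall"))
  }
  structure(list(per_class = colMeans(fold_class),
                 per_class_sd = apply(fold_class, 2L, stats::sd),
                 overall = mean(fold_overall),
                 overall_sd = stats::sd(fold_overall),
                 fold_mean = fold_overall,
                 both_empty = stats::setNames(rep(FALSE, length(fg)), fg)),
            class = "dsc_report")
}
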