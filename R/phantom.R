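#' Phantom volume specification
#'
#' Describes a synthetic multi-subfield phantom: nested ellipsoidal
#' compartments along the depth axis, one per foreground class, with
#' per-class size ranks so that large structures (Head, CA1) occupy many
#' more voxels than small ones (CA2, CA3) — the key difficulty of subfield
#' segmentation — without any anatomical modelling. Voxel intensity is the
#' class mean plus Gaussian noise, clipped to `[0, 255]`.
#'
#' @param shape Integer length-3 `(H, W, D)` voxel counts; the default
#'   matches the 112 x 103 x 24 ROI layout of subfield datasets.
#' @param class_means Numeric vector of per-class mean intensities, one per
#'   class including background. Default: background 10, foreground means
#'   evenly spaced on `[80, 240]`.
#' @param noise_sd Standard deviation of additive Gaussian intensity noise,
#'   in intensity units on the `[0, 255]` scale.
#' @param size_ranks Integer vector of ranks for the foreground classes
#'   (1 = largest). Default for the standard 10-class scheme: Head and CA1
#'   largest, CA3 and CA2 smallest.
#' @param seed Integer seed; identical spec and seed reproduce the phantom
#'   bit-identically.
#' @param scheme The [subfield_scheme()] the spec is for (fixes M).
#' @return A `phantom_spec` object.
#' @export
phantom_spec <- function(shape = c(112L, 103L, 24L), class_means = NULL,
                         noise_sd = 5, size_ranks = NULL, seed = 1L,
                         scheme = subfield_scheme()) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape <= 0L))
    stopf("shape must be three strictly positive voxel counts")
  if (noise_sd < 0) stopf("noise_sd must be non-negative")
  M <- scheme$num_classes
  if (is.null(class_means)) {
    class_means <- c(10, seq(80, 240, length.out = M - 1L))
  }
  if (length(class_means) != M)
    stopf("need exactly %d class mean intensities, got %d", M,
          length(class_means))
  if (is.null(size_ranks)) size_ranks <- default_size_ranks(scheme)
  if (length(size_ranks) != M - 1L ||
      !setequal(size_ranks, seq_len(M - 1L)))
    stopf("size_ranks must be a permutation of 1..%d (foreground classes)",
          M - 1L)
  if (noise_sd == 0 && anyDuplicated(class_means))
    warnf("noise_sd = 0 with coincident class means: classes will be indistinguishable by intensity")
  structure(list(shape = shape, class_means = as.numeric(class_means),
                 noise_sd = noise_sd, size_ranks = as.integer(size_ranks),
                 seed = as.integer(seed), scheme = scheme),
            class = "phantom_spec")
}

# Size ranks (1 = largest) by typical subfield extent for the default
# scheme; arbitrary schemes fall back to class order.
default_size_ranks <- function(scheme) {
  fg <- foreground_classes(scheme)
  canonical <- c(Head = 1L, CA1 = 2L, Tail = 3L, SUB = 4L, ERC = 5L,
                 PHG = 6L, DG = 7L, CA3 = 8L, CA2 = 9L)
  if (setequal(fg, names(canonical))) unname(canonical[fg])
  else seq_along(fg)
}

#' Slice augmentation parameters
#'
#' Augmentation enlarges a slice corpus with rotated, translated and
#' noise-perturbed copies of base slices. `factor` is the total number of
#' copies per base slice including the original, so `factor = 1` means no
#' augmentation.
#'
#' @param max_rotation_deg Maximum absolute rotation, degrees.
#' @param max_translation_px Maximum absolute translation per axis, pixels.
#' @param noise_sd Gaussian intensity noise standard deviation, on the
#'   `[0, 255]` scale.
#' @param factor Copies per base slice (>= 1).
#' @param fill_intensity Intensity assigned to pixels rotated/translated in
#'   from outside the frame (labels there are background).
#' @export
augment_params <- function(max_rotation_deg = 10, max_translation_px = 5,
                           noise_sd = 5, factor = 1L, fill_intensity = 0) {
  if (max_rotation_deg < 0 || max_translation_px < 0 || noise_sd < 0)
    stopf("augmentation magnitudes must be non-negative")
  if (factor < 1) stopf("factor must be >= 1")
  structure(list(max_rotation_deg = max_rotation_deg,
                 max_translation_px = max_translation_px,
                 noise_sd = noise_sd, factor = as.integer(factor),
                 fill_intensity = fill_intensity),
            class = "augment_params")
}

#' Generate a synthetic phantom volume
#'
#' Builds an aligned (intensity, label) volume pair. Foreground classes are
#' nested ellipsoids centred near the volume centre (with a small seeded
#' jitter per phantom); the ellipsoid of a class with a smaller size rank
#' encloses those of larger ranks, so each class occupies a shell whose
#' voxel count decreases strictly with rank.
#'
#' @param spec A [phantom_spec()].
#' @param scheme Scheme override; defaults to the spec's scheme.
#' @return A list with elements `intensity` ([intensity_volume()]) and
#'   `label` ([label_volume()]).
#' @examples
#' ph <- generate_phantom_volume(phantom_spec(shape = c(64, 64, 8), seed = 7))
#' table(ph$label$labels)
#' @export
generate_phantom_volume <- function(spec, scheme = spec$scheme) {
  stopifnot(inherits(spec, "phantom_spec"))
  M <- scheme$num_classes
  H <- spec$shape[1L]; W <- spec$shape[2L]; D <- spec$shape[3L]
  K <- M - 1L
  with_seed(spec$seed, {
    # shell weights: strictly decreasing voxel budget with rank
    w <- (K - seq_len(K) + 1L)^2
    U <- rev(cumsum(rev(w)))          # ellipsoid volume budget per rank
    t <- (U / U[1L])^(1 / 3)          # linear scale per rank
    centre <- c(H, W, D) / 2 + c(stats::runif(1, -H / 20, H / 20),
                                 stats::runif(1, -W / 20, W / 20),
                                 stats::runif(1, -D / 40, D / 40))
    base_ax <- c(H / 2 - 2, W / 2 - 2, max(D / 2 - 0.5, 1.2))
    jit <- stats::runif(K, 0.97, 1.03)

    ii <- (seq_len(H) - centre[1L])
    jj <- (seq_len(W) - centre[2L])
    kk <- (seq_len(D) - centre[3L])
    lab <- array(0L, dim = c(H, W, D))
    # paint outermost (rank 1) first; inner ellipsoids overwrite
    for (r in seq_len(K)) {
      ax <- pmax(pmin(base_ax * t[r] * jit[r], base_ax), 1.2)
      q <- outer(outer((ii / ax[1L])^2, (jj / ax[2L])^2, `+`),
                 (kk / ax[3L])^2, `+`)
      cls <- which(spec$size_ranks == r)  # foreground class index (1-based)
      lab[q <= 1] <- cls
    }
    missing <- setdiff(0:(M - 1L), sort(unique(as.vector(lab))))
    if (length(missing))
      stopf("phantom geometry left classes empty: %s (shape too small for %d classes)",
            paste(scheme$class_names[missing + 1L], collapse = ", "), M)
    vals <- spec$class_means[lab + 1L]
    if (spec$noise_sd > 0)
      vals <- vals + stats::rnorm(length(vals), 0, spec$noise_sd)
    vals <- pmin(pmax(vals, 0), 255)
    dim(vals) <- c(H, W, D)
    list(intensity = intensity_volume(vals),
         label = label_volume(lab, scheme = scheme))
  })
}

#' A single 2D image/label slice sample
#'
#' The unit of data fed to the networks: an H x W intensity slice, its
#' integer label map, and provenance (subject id, slice index, whether it is
#' an augmented copy).
#'
#' @param image Numeric H x W matrix, intensities on `[0, 255]`.
#' @param label Integer H x W matrix of class indices.
#' @param subject_id Identifier of the originating subject.
#' @param slice_index 1-based index along the depth axis.
#' @param is_augmented Logical flag.
#' @export
slice_sample <- function(image, label, subject_id, slice_index,
                         is_augmented = FALSE) {
  image <- as.matrix(image); label <- as.matrix(label)
  if (!identical(dim(image), dim(label)))
    stopf("image and label shapes differ: %s vs %s",
          paste(dim(image), collapse = "x"), paste(dim(label), collapse = "x"))
  storage.mode(label) <- "integer"
  structure(list(image = image, label = label, subject_id = subject_id,
                 slice_index = as.integer(slice_index),
                 is_augmented = isTRUE(is_augmented)),
            class = "slice_sample")
}

# Inverse-mapped affine resampling of one channel. For each output pixel the
# source location is found by rotating by -theta about the slice centre and
# subtracting the shift; `interp` is "bilinear" (images) or "nearest"
# (labels, which must never invent classes).
resample_slice <- function(x, theta_deg, shift, fill, interp) {
  H <- nrow(x); W <- ncol(x)
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  th <- theta_deg * pi / 180
  io <- rep(seq_len(H), times = W) - ci
  jo <- rep(seq_len(W), each = H) - cj
  # inverse rotation then inverse translation
  si <- cos(th) * io + sin(th) * jo - shift[1L] + ci
  sj <- -sin(th) * io + cos(th) * jo - shift[2L] + cj
  if (interp == "nearest") {
    ri <- round(si); rj <- round(sj)
    ok <- ri >= 1 & ri <= H & rj >= 1 & rj <= W
    out <- rep(fill, H * W)
    out[ok] <- x[cbind(ri[ok], rj[ok])]
  } else {
    i0 <- floor(si); j0 <- floor(sj)
    fi <- si - i0; fj <- sj - j0
    out <- rep(as.numeric(fill), H * W)
    pick <- function(ii, jj) {
      ok <- ii >= 1 & ii <= H & jj >= 1 & jj <= W
      v <- rep(as.numeric(fill), H * W)
      v[ok] <- x[cbind(ii[ok], jj[ok])]
      v
    }
    out <- (1 - fi) * (1 - fj) * pick(i0, j0) +
           fi * (1 - fj) * pick(i0 + 1, j0) +
           (1 - fi) * fj * pick(i0, j0 + 1) +
           fi * fj * pick(i0 + 1, j0 + 1)
  }
  matrix(out, nrow = H, ncol = W)
}

#' Augment one slice sample
#'
#' Applies a random rotation, translation and additive Gaussian intensity
#' noise. The image is resampled bilinearly; the label map with
#' nearest-neighbour interpolation, so no class outside the input (plus
#' background for newly exposed regions) can appear. If a draw would remove
#' the entire foreground, parameters are redrawn up to `max_retries` times.
#'
#' @param sample A [slice_sample()].
#' @param params An [augment_params()].
#' @param seed Integer seed making the augmentation reproducible.
#' @param max_retries Redraw budget for foreground-emptying transforms.
#' @return A new `slice_sample` with `is_augmented = TRUE`.
#' @export
augment_slice <- function(sample, params, seed, max_retries = 10L) {
  stopifnot(inherits(sample, "slice_sample"), inherits(params, "augment_params"))
  had_fg <- any(sample$label != 0L)
  with_seed(seed, {
    for (attempt in seq_len(max_retries)) {
      theta <- stats::runif(1, -params$max_rotation_deg, params$max_rotation_deg)
      shift <- stats::runif(2, -params$max_translation_px, params$max_translation_px)
      lab <- resample_slice(sample$label, theta, shift, fill = 0L,
                            interp = "nearest")
      if (!had_fg || any(lab != 0L)) {
        img <- resample_slice(sample$image, theta, shift,
                              fill = params$fill_intensity, interp = "bilinear")
        if (params$noise_sd > 0)
          img <- img + stats::rnorm(length(img), 0, params$noise_sd)
        img <- pmin(pmax(img, 0), 255)
        return(slice_sample(img, lab, sample$subject_id, sample$slice_index,
                            is_augmented = TRUE))
      }
    }
    stopf("augmentation emptied the foreground %d times in a row", max_retries)
  })
}

#' Build a slice corpus from synthetic subjects
#'
#' Generates `n_subjects` phantom volumes, slices each along the depth axis
#' (one base sample per slice, so `n_subjects * D` base samples), and
#' appends `factor - 1` augmented copies per base slice. Every sample —
#' base or augmented — carries its subject id, which downstream
#' cross-validation uses to keep subjects intact across splits.
#'
#' @param n_subjects Number of synthetic subjects (>= 1).
#' @param spec A [phantom_spec()]; its seed is re-derived per subject.
#' @param augment An [augment_params()]; `factor = 1` disables augmentation.
#' @param seed Master seed for subject generation and augmentation draws.
#' @param target_total Optional absolute corpus size; augmented samples
#'   beyond it are dropped deterministically (base samples are always kept).
#' @return A `seg_corpus`: list with `samples` (list of [slice_sample()]),
#'   `volumes` (per-subject intensity/label pairs), `scheme`, `n_base`.
#' @examples
#' corp <- build_corpus(2, phantom_spec(shape = c(32, 32, 4)), seed = 1)
#' length(corp$samples)  # 8
#' @export
build_corpus <- function(n_subjects, spec, augment = augment_params(),
                         seed = 1L, target_total = NULL) {
  if (n_subjects < 1L) stopf("need at least one subject")
  stopifnot(inherits(spec, "phantom_spec"))
  if (augment$factor < 1L) stopf("factor must be >= 1")
  D <- spec$shape[3L]
  seeds <- derive_seeds(seed, n_subjects * (1L + D * (augment$factor - 1L)))
  si <- 0L
  nxt <- function() { si <<- si + 1L; seeds[si] }

  volumes <- list()
  samples <- list()
  aug_samples <- list()
  for (s in seq_len(n_subjects)) {
    sid <- sprintf("subject%02d", s)
    sspec <- spec
    sspec$seed <- nxt()
    ph <- generate_phantom_volume(sspec)
    volumes[[sid]] <- ph
    base <- extract_slices(ph$intensity, ph$label, sid)
    samples <- c(samples, base)
    if (augment$factor > 1L) {
      for (b in base) {
        for (rep in seq_len(augment$factor - 1L)) {
          aug_samples[[length(aug_samples) + 1L]] <-
            augment_slice(b, augment, seed = nxt())
        }
      }
    }
  }
  n_base <- length(samples)
  if (!is.null(target_total)) {
    if (target_total < n_base)
      stopf("target_total (%d) below base sample count (%d)", target_total,
            n_base)
    aug_samples <- aug_samples[seq_len(min(length(aug_samples),
                                           target_total - n_base))]
  }
  structure(list(samples = c(samples, aug_samples), volumes = volumes,
                 scheme = spec$scheme, spec = spec, augment = augment,
                 n_base = n_base, seed = as.integer(seed)),
            class = "seg_corpus")
}

#' @export
print.seg_corpus <- function(x, ...) {
  cat(sprintf("<seg_corpus> %d samples (%d base) from %d subjects, %d classes\n",
              length(x$samples), x$n_base, length(x$volumes),
              x$scheme$num_classes))
  invisible(x)
}

corpus_subjects <- function(corpus) names(corpus$volumes)
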