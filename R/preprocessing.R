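#' Linear intensity normalization to [0, 255]
#'
#' Applies the affine map `v -> 255 * (v - min) / (max - min)` so the output
#' spans exactly `[0, 255]`. A constant volume (max == min) is mapped to all
#' zeros with a warning rather than an error, so batch pipelines keep
#' running; the convention is documented here. Idempotent on
#' already-normalized non-constant volumes.
#'
#' @param volume An [intensity_volume()].
#' @return A normalized [intensity_volume()].
#' @export
normalize_intensity <- function(volume) {
  stopifnot(inherits(volume, "intensity_volume"))
  v <- volume$values
  lo <- min(v); hi <- max(v)
  if (hi == lo) {
    warnf("constant volume (value %g): normalizing to all zeros", lo)
    v[] <- 0
  } else {
    v <- 255 * (v - lo) / (hi - lo)
  }
  intensity_volume(v, spacing = volume$spacing)
}

#' Extract a region of interest
#'
#' Copies a `size`-shaped sub-volume starting at 0-based `origin` (half-open
#' ranges, no resampling). The canonical subfield ROI is 112 x 103 x 24.
#'
#' @param volume An [intensity_volume()] or [label_volume()].
#' @param origin Integer length-3, 0-based crop origin `(i, j, k)`.
#' @param size Integer length-3 crop shape `(H, W, D)`.
#' @return A volume of the same type with spatial shape exactly `size`.
#' @export
extract_roi <- function(volume, origin, size) {
  origin <- as.integer(origin); size <- as.integer(size)
  arr <- if (inherits(volume, "intensity_volume")) volume$values
         else if (inherits(volume, "label_volume")) volume$labels
         else stopf("expected an intensity_volume or label_volume")
  d <- dim(arr)
  axes <- c("i", "j", "k")
  for (a in 1:3) {
    if (origin[a] < 0L || origin[a] + size[a] > d[a])
      stopf("ROI out of bounds on axis %s: origin %d + size %d > extent %d",
            axes[a], origin[a], size[a], d[a])
  }
  sub <- arr[origin[1L] + seq_len(size[1L]),
             origin[2L] + seq_len(size[2L]),
             origin[3L] + seq_len(size[3L]), drop = FALSE]
  if (inherits(volume, "intensity_volume"))
    intensity_volume(sub, spacing = volume$spacing)
  else label_volume(sub, scheme = volume$scheme, spacing = volume$spacing)
}

#' Slice a volume pair into 2D samples
#'
#' Cuts the aligned intensity and label volumes along the depth (third)
#' axis, producing one [slice_sample()] per depth index in order.
#' [stack_slices()] is the exact inverse.
#'
#' @param intensity An [intensity_volume()].
#' @param label The aligned [label_volume()].
#' @param subject_id Subject identifier stamped on each sample.
#' @return List of `D` [slice_sample()] objects.
#' @export
extract_slices <- function(intensity, label, subject_id = "subject") {
  stopifnot(inherits(intensity, "intensity_volume"),
            inherits(label, "label_volume"))
  if (!identical(dim(intensity$values), dim(label$labels)))
    stopf("intensity and label volume shapes differ")
  D <- dim(intensity$values)[3L]
  lapply(seq_len(D), function(k)
    slice_sample(intensity$values[, , k], label$labels[, , k],
                 subject_id = subject_id, slice_index = k))
}

#' @param slices List of [slice_sample()]s in depth order.
#' @param scheme Scheme for the rebuilt label volume.
#' @rdname extract_slices
#' @return `stack_slices`: list with `intensity` and `label` volumes rebuilt
#'   from the slices.
#' @export
stack_slices <- function(slices, scheme = subfield_scheme()) {
  if (!length(slices)) stopf("no slices to stack")
  H <- nrow(slices[[1L]]$image); W <- ncol(slices[[1L]]$image)
  D <- length(slices)
  vals <- array(0, dim = c(H, W, D))
  labs <- array(0L, dim = c(H, W, D))
  for (k in seq_len(D)) {
    vals[, , k] <- slices[[k]]$image
    labs[, , k] <- slices[[k]]$label
  }
  list(intensity = intensity_volume(vals),
       label = label_volume(labs, scheme = scheme))
}

#' One-hot encode a label map
#'
#' Expands an H x W integer label map into an H x W x M indicator array:
#' each pixel's M-vector has a single 1 at its class index (0-based classes
#' map to channels 1..M). `argmax` over channels inverts the encoding.
#'
#' @param label Integer H x W matrix with values in `[0, M-1]`.
#' @param M Number of classes.
#' @return Numeric H x W x M indicator array.
#' @export
one_hot_encode <- function(label, M) {
  label <- as.matrix(label)
  bad <- which(label < 0L | label >= M | is.na(label), arr.ind = TRUE)
  if (nrow(bad))
    stopf("label %s at pixel (%d, %d) outside [0, %d]",
          as.character(label[bad[1L, , drop = FALSE]]), bad[1L, 1L],
          bad[1L, 2L], M - 1L)
  H <- nrow(label); W <- ncol(label)
  out <- array(0, dim = c(H, W, M))
  idx <- cbind(rep(seq_len(H), times = W), rep(seq_len(W), each = H),
               as.vector(label) + 1L)
  out[idx] <- 1
  out
}
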