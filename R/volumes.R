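#' Aligned intensity and label volumes
#'
#' Lightweight containers for a 3D intensity grid and its voxel-aligned
#' integer class-label grid. Both wrap plain R arrays; `spacing` is carried
#' as informational metadata only.
#'
#' @param values Numeric 3D array of intensities.
#' @param spacing Numeric length-3 voxel size per axis (informational).
#' @return An `intensity_volume` object.
#' @export
intensity_volume <- function(values, spacing = c(1, 1, 1)) {
  values <- unclass(values)
  if (length(dim(values)) != 3L) stopf("intensity volume must be 3D")
  if (!all(is.finite(values))) stopf("intensity volume contains non-finite values")
  structure(list(values = values, spacing = as.numeric(spacing)),
            class = "intensity_volume")
}

#' @param labels Integer 3D array of class indices in `[0, M-1]`.
#' @param scheme A [subfield_scheme()] giving names to the indices.
#' @rdname intensity_volume
#' @export
label_volume <- function(labels, scheme = subfield_scheme(),
                         spacing = c(1, 1, 1)) {
  labels <- unclass(labels)
  if (length(dim(labels)) != 3L) stopf("label volume must be 3D")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L || max(labels) >= scheme$num_classes)
    stopf("labels must be integers in [0, %d]", scheme$num_classes - 1L)
  structure(list(labels = labels, scheme = scheme,
                 spacing = as.numeric(spacing)),
            class = "label_volume")
}

#' @export
print.intensity_volume <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_volume> %dx%dx%d, range [%.1f, %.1f]\n",
              d[1], d[2], d[3], min(x$values), max(x$values)))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %dx%dx%d, %d classes\n",
              d[1], d[2], d[3], x$scheme$num_classes))
  invisible(x)
}

#' @export
dim.intensity_volume <- function(x) dim(x$values)

#' @export
dim.label_volume <- function(x) dim(x$labels)

#' Read and write volumes as NIfTI
#'
#' Intensity volumes are written as floating-point NIfTI; label volumes as
#' integer-typed NIfTI so class indices survive the round trip exactly.
#'
#' @param volume An `intensity_volume` or `label_volume`.
#' @param path Path to a `.nii` or `.nii.gz` file.
#' @export
write_volume_nifti <- function(volume, path) {
  if (inherits(volume, "intensity_volume")) {
    arr <- volume$values; dtype <- "double"
  } else if (inherits(volume, "label_volume")) {
    arr <- volume$labels; dtype <- "int16"
  } else stopf("expected an intensity_volume or label_volume")
  attr(arr, "pixdim") <- volume$spacing
  RNifti::writeNifti(RNifti::asNifti(arr, datatype = dtype), path)
  invisible(path)
}

#' @rdname write_volume_nifti
#' @export
read_intensity_nifti <- function(path) {
  img <- RNifti::readNifti(path)
  intensity_volume(array(as.numeric(img), dim = dim(img)),
                   spacing = RNifti::pixdim(img)[seq_len(3)])
}

#' @param scheme Scheme used to validate and name the label indices.
#' @rdname write_volume_nifti
#' @export
read_label_nifti <- function(path, scheme = subfield_scheme()) {
  img <- RNifti::readNifti(path)
  label_volume(array(as.integer(img), dim = dim(img)), scheme = scheme,
               spacing = RNifti::pixdim(img)[seq_len(3)])
}
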