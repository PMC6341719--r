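#' Save and load network checkpoints
#'
#' Single-file checkpoints with a versioned header; the architecture is
#' stored alongside the weights and validated on load, so a checkpoint
#' cannot silently be applied to a mismatched network.
#'
#' @param params A `generator_params` or `adversary_params` object.
#' @param path Destination file.
#' @export
save_checkpoint <- function(params, path) {
  kind <- if (inherits(params, "generator_params")) "generator"
          else if (inherits(params, "adversary_params")) "adversary"
          else stopf("expected generator_params or adversary_params")
  obj <- list(format = "adverseg-checkpoint", version = 1L, kind = kind,
              arch = attr(params, "arch"), weights = unclass(params))
  attr(obj$weights, "arch") <- NULL
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @return `load_checkpoint` returns the restored parameter object.
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "adverseg-checkpoint"))
    stopf("'%s' is not an adverseg checkpoint", path)
  if (obj$version != 1L)
    stopf("unsupported checkpoint version %s", obj$version)
  cls <- paste0(obj$kind, "_params")
  structure(obj$weights, arch = obj$arch, class = cls)
}
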