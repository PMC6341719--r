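#' Subfield labelling scheme
#'
#' Defines the ordered set of class labels used throughout the package. The
#' default scheme is the standard hippocampal subfield protocol: background
#' plus the nine subfields CA1, CA2, DG, CA3, Head, Tail, SUB, ERC and PHG
#' (M = 10 classes). Class index 0 is always background; foreground classes
#' take indices 1..M-1 in the order given.
#'
#' @param class_names Character vector of unique class names; the first entry
#'   is the background class.
#' @return An object of class `subfield_scheme` with elements `class_names`
#'   and `num_classes`.
#' @examples
#' sch <- subfield_scheme()
#' sch$num_classes  # 10
#' @export
subfield_scheme <- function(class_names = c("background", "CA1", "CA2", "DG",
                                            "CA3", "Head", "Tail", "SUB",
                                            "ERC", "PHG")) {
  if (anyDuplicated(class_names)) stopf("class names must be unique")
  if (length(class_names) < 2L)
    stopf("a scheme needs background plus at least one foreground class")
  structure(list(class_names = as.character(class_names),
                 num_classes = length(class_names)),
            class = "subfield_scheme")
}

#' @export
print.subfield_scheme <- function(x, ...) {
  cat("<subfield_scheme> ", x$num_classes, " classes: ",
      paste(x$class_names, collapse = ", "), "\n", sep = "")
  invisible(x)
}

foreground_classes <- function(scheme) scheme$class_names[-1L]
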