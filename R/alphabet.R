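#' Interaction-type alphabets
#'
#' A type alphabet is the set of interaction types that links of a network
#' can carry, e.g. `synergistic < additive < antagonistic` (K = 3) for
#' exhaustive pairwise screens, or `none / interaction` (K = 2) for adverse
#' interaction databases that list only positive links.  An alphabet may be
#' `ordered`, meaning the label order is a semantic severity scale, which is
#' what the within-one-level classification metric requires.
#'
#' @param labels character vector of at least two distinct type names, in
#'   scale order if `ordered = TRUE`.
#' @param ordered logical; is the label order a semantic scale?
#' @return An object of class `type_alphabet` with fields `labels`,
#'   `ordered` and `K = length(labels)`.
#' @examples
#' type_alphabet(c("synergistic", "additive", "antagonistic"), ordered = TRUE)
#' @export
type_alphabet <- function(labels, ordered = FALSE) {
  labels <- as.character(labels)
  if (length(labels) < 2L)
    stop("a type alphabet needs at least two labels (K >= 2)")
  if (anyDuplicated(labels))
    stop("type labels must be unique")
  structure(list(labels = labels, ordered = isTRUE(ordered),
                 K = length(labels)),
            class = "type_alphabet")
}

#' @rdname type_alphabet
#' @details `binary_alphabet()` is the two-type alphabet
#'   `none < interaction` used for sparse interaction databases, where a
#'   stored link means "interaction" and an absent pair means "none".
#' @export
binary_alphabet <- function() {
  type_alphabet(c("none", "interaction"), ordered = TRUE)
}

is_binary_alphabet <- function(alphabet) {
  alphabet$K == 2L && identical(alphabet$labels, c("none", "interaction"))
}

#' @export
print.type_alphabet <- function(x, ...) {
  sep <- if (x$ordered) " < " else ", "
  cat("Type alphabet (K = ", x$K, if (x$ordered) ", ordered" else "",
      "): ", paste(x$labels, collapse = sep), "\n", sep = "")
  invisible(x)
}

# map labels to 1-based type indices, erroring on unknown labels
type_index <- function(labels, alphabet, context = "type") {
  idx <- match(labels, alphabet$labels)
  if (anyNA(idx)) {
    bad <- unique(labels[is.na(idx)])
    stop(sprintf("unknown %s label(s): %s (alphabet: %s)", context,
                 paste(bad, collapse = ", "),
                 paste(alphabet$labels, collapse = ", ")))
  }
  idx
}
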