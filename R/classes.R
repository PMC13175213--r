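#' Pathogenic-mechanism classes
#'
#' The four collagen VI phenotype classes used throughout the package, with
#' their fixed integer coding: 1 = `control`, 2 = `glycine_substitution`,
#' 3 = `pseudoexon_insertion`, 4 = `exon_skipping`. The three non-control
#' classes are the dominant-negative pathogenic mechanisms; `control` is the
#' unaffected phenotype.
#'
#' @return A tibble with columns `label` (character) and `index` (integer).
#' @examples
#' pathogenic_classes()
#' @export
pathogenic_classes <- function() {
  tibble::tibble(
    label = c("control", "glycine_substitution", "pseudoexon_insertion",
              "exon_skipping"),
    index = 1:4
  )
}

#' @rdname pathogenic_classes
#' @export
class_labels <- function() pathogenic_classes()$label

#' Convert class labels to indices (and back)
#'
#' @param label Character vector of class labels.
#' @param index Integer vector of class indices in 1..4.
#' @return `class_index()` returns integers; `class_label()` returns characters.
#' @export
class_index <- function(label) {
  idx <- match(label, class_labels())
  if (anyNA(idx)) {
    bad <- unique(label[is.na(idx)])
    stop("unknown class label(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  idx
}

#' @rdname class_index
#' @export
class_label <- function(index) {
  if (any(index < 1L | index > 4L | index != round(index))) {
    stop("class index out of range 1..4", call. = FALSE)
  }
  class_labels()[index]
}

# Derive a per-item 32-bit seed from a root seed and a counter, so that
# generation order is immaterial: item i always gets the same stream
# regardless of which items are generated around it. Plain LCG mixing;
# stays below 2^31 - 1.
derive_seed <- function(root_seed, counter) {
  root <- as.double(root_seed %% 2147483647)
  ((root * 2654435.0 + 12345) %% 2147483647 + 97 * as.double(counter)) %%
    2147483647
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is untouched.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stopifnot_image <- function(pixels) {
  if (!(is.array(pixels) && length(dim(pixels)) == 3 && dim(pixels)[3] == 3)) {
    stop("expected an H x W x 3 pixel array", call. = FALSE)
  }
  invisible(pixels)
}
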