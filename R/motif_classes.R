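#' Define a calcium-dependent anchor-spacing motif class
#'
#' A motif class is named after the 1-based positions of its hydrophobic
#' anchors within the motif window ("1-10" means anchors at positions 1 and
#' 10) and is represented internally by zero-based relative offsets, so
#' 1-10 is `c(0, 9)` and 1-5-10 is `c(0, 4, 9)`.
#'
#' @param name class label, e.g. `"1-10"` or a custom label.
#' @param offsets strictly increasing integer vector of relative anchor
#'   offsets, starting at 0.
#' @return an object of class `motif_class` with fields `name`, `offsets`
#'   and `span` (last offset + 1, the motif window length).
#' @examples
#' motif_class("1-10", c(0, 9))
#' motif_class("1-8-14", c(0, 7, 13))  # custom spacing
#' @export
motif_class <- function(name, offsets) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  offsets <- as.integer(offsets)
  if (length(offsets) < 1L || offsets[1] != 0L) {
    stop("motif class offsets must start at 0", call. = FALSE)
  }
  if (length(offsets) > 1L && any(diff(offsets) <= 0L)) {
    stop("motif class offsets must be strictly increasing", call. = FALSE)
  }
  structure(list(name = name, offsets = offsets,
                 span = offsets[length(offsets)] + 1L),
            class = "motif_class")
}

#' @export
print.motif_class <- function(x, ...) {
  cat("<motif_class> ", x$name, ": offsets (",
      paste(x$offsets, collapse = ", "), "), span ", x$span, "\n", sep = "")
  invisible(x)
}

#' The default roster of calcium-dependent motif classes
#'
#' The canonical anchor-spacing classes: 1-10, 1-12, 1-14, 1-16 (two
#' anchors) and 1-5-10, 1-5-8-14 (three and four anchors).  Custom classes
#' can be built with [motif_class()] and passed alongside or instead of
#' these.
#'
#' @return named list of [motif_class()] objects.
#' @export
default_motif_classes <- function() {
  classes <- list(
    motif_class("1-10", c(0L, 9L)),
    motif_class("1-12", c(0L, 11L)),
    motif_class("1-14", c(0L, 13L)),
    motif_class("1-16", c(0L, 15L)),
    motif_class("1-5-10", c(0L, 4L, 9L)),
    motif_class("1-5-8-14", c(0L, 4L, 7L, 13L))
  )
  names(classes) <- vapply(classes, function(k) k$name, character(1))
  classes
}

# Coerce a single class, class name, or list thereof to a named list of
# motif_class objects; duplicate names are a configuration error.
as_motif_classes <- function(classes) {
  if (inherits(classes, "motif_class")) classes <- list(classes)
  stopifnot(is.list(classes) || is.character(classes))
  if (is.character(classes)) {
    roster <- default_motif_classes()
    unknown <- setdiff(classes, names(roster))
    if (length(unknown) > 0L) {
      stop("unknown motif class name(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    classes <- roster[classes]
  }
  if (length(classes) == 0L) stop("no motif classes given", call. = FALSE)
  if (!all(vapply(classes, inherits, logical(1), "motif_class"))) {
    stop("classes must be motif_class objects or default class names",
         call. = FALSE)
  }
  nm <- vapply(classes, function(k) k$name, character(1))
  if (anyDuplicated(nm)) {
    stop("duplicate motif class names: ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  names(classes) <- nm
  classes
}
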