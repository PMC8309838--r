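#' Construct a breast ROI temperature matrix
#'
#' Wraps a rectangular grid of skin temperatures (degrees Celsius) for one
#' pre-segmented breast together with a binary tissue mask. Masked-out cells
#' are background and never contribute to texture statistics.
#'
#' @param values numeric matrix of temperatures.
#' @param mask binary matrix of the same shape (1 = breast tissue); defaults
#'   to all ones.
#' @param side `"left"` or `"right"`.
#' @return A `roi_matrix` object.
#' @export
roi_matrix <- function(values, mask = NULL, side = c("left", "right")) {
  side <- match.arg(side)
  if (!is.matrix(values) || !is.numeric(values)) {
    abort("values must be a numeric matrix")
  }
  if (is.null(mask)) mask <- matrix(1L, nrow(values), ncol(values))
  if (!all(dim(mask) == dim(values))) {
    abort("mask and values must have identical shape")
  }
  mask <- matrix(as.integer(mask != 0), nrow(values), ncol(values))
  if (sum(mask) < 16) abort("mask must have at least 16 active cells")
  if (any(!is.finite(values[mask == 1]))) {
    abort("non-finite temperature inside the mask")
  }
  structure(list(values = values, mask = mask, side = side),
            class = "roi_matrix")
}

#' Pair the two breast ROIs of one exam
#'
#' @param left,right `roi_matrix` objects with matching sides.
#' @param label optional class label, `"cancer"` or `"no_cancer"`.
#' @param exam_id exam identifier.
#' @return A `roi_pair` object.
#' @export
roi_pair <- function(left, right, label = NULL, exam_id = "exam") {
  stopifnot(inherits(left, "roi_matrix"), inherits(right, "roi_matrix"))
  if (left$side != "left" || right$side != "right") {
    abort("sides must be distinct: left ROI first, right ROI second")
  }
  if (!is.null(label)) {
    label <- as.character(label)
    if (!label %in% CLASS_LEVELS) {
      abort(sprintf("label must be one of: %s", paste(CLASS_LEVELS, collapse = ", ")))
    }
  }
  structure(list(left = left, right = right, label = label,
                 exam_id = as.character(exam_id)),
            class = "roi_pair")
}

#' @export
print.roi_matrix <- function(x, ...) {
  v <- x$values[x$mask == 1]
  cat(sprintf("%s breast ROI: %d x %d, %d masked-in cells, %.2f-%.2f degC\n",
              x$side, nrow(x$values), ncol(x$values), sum(x$mask),
              min(v), max(v)))
  invisible(x)
}

#' @export
print.roi_pair <- function(x, ...) {
  cat(sprintf("Exam %s (%s)\n", x$exam_id, x$label %||% "unlabeled"))
  print(x$left); print(x$right)
  invisible(x)
}
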