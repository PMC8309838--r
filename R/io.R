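# Plain-text readers and writers: whitespace-delimited temperature grids
# (one file per breast) and the CSV feature-table dialect.

#' Read a temperature matrix from a whitespace-delimited text file
#'
#' Parses the plain-text grid dialect used by public thermography archives:
#' one row of whitespace-separated Celsius values per line. Ragged rows and
#' non-numeric tokens are reported with their position.
#'
#' @param path file path.
#' @param mask_path optional path to a 0/1 text grid of the same shape.
#' @param side `"left"` or `"right"`.
#' @return A [roi_matrix()].
#' @export
read_temperature_matrix <- function(path, mask_path = NULL,
                                    side = c("left", "right")) {
  side <- match.arg(side)
  values <- parse_numeric_grid(path)
  mask <- NULL
  if (!is.null(mask_path)) {
    mask <- parse_numeric_grid(mask_path)
    if (!all(dim(mask) == dim(values))) {
      abort(sprintf("mask %s shape %dx%d does not match matrix shape %dx%d",
                    mask_path, nrow(mask), ncol(mask), nrow(values), ncol(values)))
    }
  }
  roi_matrix(values, mask = mask, side = side)
}

parse_numeric_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) abort(sprintf("empty grid file: %s", path))
  rows <- lapply(seq_along(lines), function(ln) {
    toks <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    vals <- suppressWarnings(as.numeric(toks))
    if (anyNA(vals)) {
      bad <- which(is.na(vals))[1]
      abort(sprintf("non-numeric token '%s' at line %d, position %d of %s",
                    toks[bad], ln, bad, path))
    }
    vals
  })
  widths <- lengths(rows)
  if (length(unique(widths)) > 1) {
    bad <- which(widths != widths[1])[1]
    abort(sprintf("ragged grid: line %d of %s has %d values, expected %d",
                  bad, path, widths[bad], widths[1]))
  }
  do.call(rbind, rows)
}

#' Write a temperature matrix as whitespace-delimited text
#' @param roi a [roi_matrix()] or plain numeric matrix.
#' @param path destination file.
#' @param digits significant digits to keep.
#' @export
write_temperature_matrix <- function(roi, path, digits = 10) {
  values <- if (inherits(roi, "roi_matrix")) roi$values else roi
  lines <- apply(values, 1, function(r) {
    paste(format(r, digits = digits, trim = TRUE, scientific = FALSE),
          collapse = " ")
  })
  writeLines(lines, path)
  invisible(path)
}

#' Read a feature table from CSV
#'
#' Expects the dialect written by [write_feature_table()]: a header row,
#' `exam_id` first, feature columns, and a final `class` column restricted to
#' `cancer` / `no_cancer`.
#'
#' @param path CSV file path.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  if (nrow(df) == 0 || ncol(df) == 0) abort(sprintf("empty feature table: %s", path))
  if (!"class" %in% names(df)) {
    abort(sprintf("missing 'class' column in %s", path))
  }
  as_class_factor(df$class)  # validates tokens
  tibble::as_tibble(df)
}

#' Write a feature table to CSV
#' @param data feature table (tibble or data frame).
#' @param path destination file.
#' @export
write_feature_table <- function(data, path) {
  stopifnot(is.data.frame(data))
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}
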