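#' Parcellated brain map
#'
#' A brain map is a single scalar value per parcel: gene expression, GBC,
#' a change in GBC, a principal component, a regression coefficient map, etc.
#' Labels are the only join key across files; operations combining a map
#' with a connectome align by label.
#'
#' @param values numeric vector of finite parcel values.
#' @param labels character vector of parcel identifiers.
#' @return An object of class `brain_map` with elements `values` (named) and
#'   `labels`.
#' @export
brain_map <- function(values, labels = names(values)) {
  if (is.null(labels)) labels <- paste0("p", seq_along(values))
  labels <- as.character(labels)
  values <- as.numeric(values)
  if (length(values) != length(labels)) stop("values/labels length mismatch")
  if (any(!is.finite(values))) stop("brain map values must be finite")
  if (anyDuplicated(labels)) stop("duplicate parcel labels")
  names(values) <- labels
  structure(list(values = values, labels = labels), class = "brain_map")
}

#' @export
print.brain_map <- function(x, ...) {
  cat(sprintf("Brain map: %d parcels, range [%.4g, %.4g]\n",
              length(x$values), min(x$values), max(x$values)))
  invisible(x)
}

#' @export
as.numeric.brain_map <- function(x, ...) unname(x$values)

#' Align a brain map to a label order
#'
#' @param map a `brain_map`.
#' @param labels target label order (e.g. `sc$labels`).
#' @return A `brain_map` reordered to `labels`.
#' @export
align_map <- function(map, labels) {
  stopifnot(inherits(map, "brain_map"))
  missing <- setdiff(labels, map$labels)
  if (length(missing))
    stop("map is missing parcel(s): ", paste(missing, collapse = ", "))
  brain_map(map$values[labels], labels)
}

#' Read / write brain maps as two-column delimited text
#'
#' The on-disk format is a header line `label<sep>value` followed by one row
#' per parcel. Round-trips are lossless to full double precision (values are
#' written with 17 significant digits) and label order is preserved.
#'
#' @param path file path.
#' @param sep field separator; default tab, comma auto-detected on read.
#' @return `read_brain_map` returns a `brain_map`.
#' @export
read_brain_map <- function(path, sep = "\t") {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("brain map file has no data rows: ", path)
  if (!grepl(sep, lines[[1]], fixed = TRUE) && grepl(",", lines[[1]], fixed = TRUE))
    sep <- ","
  df <- utils::read.table(text = lines, header = TRUE, sep = sep,
                          colClasses = c("character", "character"),
                          check.names = FALSE)
  if (ncol(df) != 2L) stop("brain map file must have exactly two columns")
  vals <- suppressWarnings(as.numeric(df[[2]]))
  if (any(is.na(vals))) {
    bad <- which(is.na(vals))[1]
    stop(sprintf("non-numeric value at line %d of %s", bad + 1L, path))
  }
  dup <- df[[1]][duplicated(df[[1]])]
  if (length(dup))
    stop("duplicate label(s) in ", path, ": ", paste(unique(dup), collapse = ", "))
  brain_map(vals, df[[1]])
}

#' @rdname read_brain_map
#' @param map a `brain_map` to write.
#' @export
write_brain_map <- function(map, path, sep = "\t") {
  stopifnot(inherits(map, "brain_map"))
  lines <- c(paste("label", "value", sep = sep),
             paste(map$labels, formatC(map$values, digits = 17, format = "g"),
                   sep = sep))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write labeled square matrices as delimited text
#'
#' Format: header row of parcel labels, then one row per parcel with the
#' label in the first field. Lossless round trip at 17 significant digits.
#'
#' @param path file path.
#' @param sep field separator; default tab, comma auto-detected on read.
#' @return `read_matrix` returns a labeled square numeric matrix.
#' @export
read_matrix <- function(path, sep = "\t") {
  first <- readLines(path, n = 1L, encoding = "UTF-8")
  if (!grepl(sep, first, fixed = TRUE) && grepl(",", first, fixed = TRUE))
    sep <- ","
  df <- utils::read.table(path, header = TRUE, sep = sep, row.names = 1L,
                          check.names = FALSE)
  m <- as.matrix(df)
  if (nrow(m) != ncol(m)) stop("matrix in ", path, " is not square")
  if (!is.numeric(m)) stop("non-numeric entries in ", path)
  if (anyDuplicated(rownames(m))) stop("duplicate row labels in ", path)
  m
}

#' @rdname read_matrix
#' @param m labeled square numeric matrix to write.
#' @export
write_matrix <- function(m, path, sep = "\t") {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("matrix must be square")
  labels <- rownames(m)
  if (is.null(labels)) labels <- paste0("p", seq_len(nrow(m)))
  header <- paste(c("label", labels), collapse = sep)
  rows <- vapply(seq_len(nrow(m)), function(i) {
    paste(c(labels[i], formatC(m[i, ], digits = 17, format = "g")),
          collapse = sep)
  }, character(1))
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}
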