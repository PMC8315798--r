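#' Structural connectome container
#'
#' Bundles a parcellated structural connectivity matrix with parcel labels
#' and (optionally) an inter-parcel distance matrix. The diagonal is set to
#' zero (local coupling is modeled explicitly) and each row is normalized to
#' sum to one, so that total long-range input to every node is balanced.
#' Normalization happens once, here, and is never silently re-applied.
#'
#' @param C square numeric matrix of non-negative connection weights.
#' @param labels character vector of parcel identifiers; defaults to the
#'   dimnames of `C` or `"p1"..."pN"`.
#' @param D optional symmetric inter-parcel distance matrix (mm) with zero
#'   diagonal.
#' @param normalize if `TRUE` (default) zero the diagonal and row-normalize.
#'   Set to `FALSE` only for matrices already normalized by this function.
#' @return An object of class `dmf_connectome` with elements `C`, `labels`,
#'   `D`, and `n`.
#' @examples
#' sc <- make_connectome(n_nodes = 10, seed = 1)
#' rowSums(sc$C)
#' @export
dmf_connectome <- function(C, labels = NULL, D = NULL, normalize = TRUE) {
  C <- as.matrix(C)
  if (nrow(C) != ncol(C)) stop("connectome matrix must be square")
  if (any(!is.finite(C))) stop("connectome weights must be finite")
  if (any(C < 0)) stop("connectome weights must be non-negative")
  n <- nrow(C)
  if (is.null(labels)) labels <- rownames(C)
  if (is.null(labels)) labels <- paste0("p", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n) stop("labels length must match matrix dimension")
  if (anyDuplicated(labels)) stop("duplicate parcel labels")
  if (normalize) {
    diag(C) <- 0
    rs <- rowSums(C)
    if (any(rs <= 0)) stop("every node needs at least one positive weight")
    C <- C / rs
  } else {
    if (any(diag(C) != 0)) stop("diagonal must be zero")
    if (max(abs(rowSums(C) - 1)) > 1e-8)
      stop("matrix is not row-normalized; use normalize = TRUE")
  }
  dimnames(C) <- list(labels, labels)
  if (!is.null(D)) {
    D <- as.matrix(D)
    if (!all(dim(D) == n)) stop("distance matrix dimension mismatch")
    if (max(abs(D - t(D))) > 1e-8) stop("distance matrix must be symmetric")
    if (any(diag(D) != 0)) stop("distance matrix diagonal must be zero")
    dimnames(D) <- list(labels, labels)
  }
  structure(list(C = C, labels = labels, D = D, n = n),
            class = "dmf_connectome")
}

#' @export
print.dmf_connectome <- function(x, ...) {
  cat(sprintf("Structural connectome: %d parcels, row-normalized%s\n",
              x$n, if (is.null(x$D)) "" else ", with distances"))
  invisible(x)
}

#' Read a structural connectome from delimited text
#'
#' Expects a square matrix with a header row and first column of parcel
#' labels (see [write_matrix()]). An optional distance matrix is aligned to
#' the connectome by label, not by position.
#'
#' @param path path to the connectivity matrix file.
#' @param distance_path optional path to a distance matrix file.
#' @param sep field separator (default `"\t"`, auto-detects `","`).
#' @return A [dmf_connectome()] object.
#' @export
read_connectome <- function(path, distance_path = NULL, sep = "\t") {
  C <- read_matrix(path, sep = sep)
  D <- NULL
  if (!is.null(distance_path)) {
    D <- read_matrix(distance_path, sep = sep)
    if (!setequal(rownames(D), rownames(C)))
      stop("distance matrix labels do not match connectome labels")
    D <- D[rownames(C), rownames(C)]
  }
  dmf_connectome(C, labels = rownames(C), D = D, normalize = TRUE)
}
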