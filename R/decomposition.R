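#' Principal component analysis of a map ensemble
#'
#' Eigendecomposition of the spatial covariance `C = X^T X / (M - 1)` of an
#' ensemble of M brain maps over N parcels, after column (parcel-wise) mean
#' subtraction. Principal components are ordered by descending eigenvalue;
#' at most `M - 1` eigenvalues are nonzero. The sign of each component is
#' fixed so that its largest-magnitude element is positive (eigenvectors are
#' sign-ambiguous).
#'
#' @param X numeric M x N matrix (rows = maps, columns = parcels).
#' @return Object of class `map_pca`: `P` (N x N, columns = PCs), `lambda`
#'   (descending eigenvalues, negatives clipped at zero), `var_frac`,
#'   `center` (removed column means), `scores` (centered `X` projected on
#'   `P`).
#' @export
map_pca <- function(X) {
  X <- as.matrix(X)
  M <- nrow(X)
  if (M < 2L) stop("PCA needs at least two maps")
  center <- colMeans(X)
  Xc <- sweep(X, 2L, center)
  C <- crossprod(Xc) / (M - 1)
  e <- eigen(C, symmetric = TRUE)
  lambda <- pmax(e$values, 0)
  P <- e$vectors
  for (j in seq_len(ncol(P))) {
    i_max <- which.max(abs(P[, j]))
    if (P[i_max, j] < 0) P[, j] <- -P[, j]
  }
  colnames(P) <- paste0("PC", seq_len(ncol(P)))
  if (!is.null(colnames(X))) rownames(P) <- colnames(X)
  structure(list(P = P, lambda = lambda, var_frac = lambda / sum(lambda),
                 center = center, scores = Xc %*% P),
            class = "map_pca")
}

#' @export
print.map_pca <- function(x, ...) {
  k <- min(5L, length(x$lambda))
  cat(sprintf("Map-ensemble PCA: %d parcels\n", nrow(x$P)))
  cat("  leading variance fractions:",
      paste(sprintf("%.3f", x$var_frac[seq_len(k)]), collapse = ", "), "\n")
  invisible(x)
}

#' Permutation test for principal component significance
#'
#' Null distribution of per-component variance fractions under independent
#' random spatial permutation of every map (each row of `X` is shuffled
#' independently), which destroys shared spatial structure while preserving
#' each map's value distribution. A component is flagged significant when
#' its observed variance fraction exceeds the null's 95th percentile; both
#' the 5th and 95th null percentiles are returned per component.
#'
#' @param X M x N matrix of maps.
#' @param n_perm number of permutations (default 1000; fewer than 100 draws
#'   a warning).
#' @param seed RNG seed.
#' @return Object of class `pc_perm_test`: `var_frac` (observed), `null`
#'   (n_perm x n_pc matrix), `p95`, `p05`, `significant`.
#' @export
pc_permutation_test <- function(X, n_perm = 1000, seed = 1) {
  X <- as.matrix(X)
  if (n_perm < 100) warning("fewer than 100 permutations")
  obs <- map_pca(X)$var_frac
  set.seed(seed)
  null <- matrix(NA_real_, n_perm, length(obs))
  for (p in seq_len(n_perm)) {
    Xp <- t(apply(X, 1L, sample))
    null[p, ] <- map_pca(Xp)$var_frac
  }
  p95 <- apply(null, 2L, stats::quantile, probs = 0.95, names = FALSE)
  p05 <- apply(null, 2L, stats::quantile, probs = 0.05, names = FALSE)
  structure(list(var_frac = obs, null = null, p95 = p95, p05 = p05,
                 significant = obs > p95),
            class = "pc_perm_test")
}

#' @export
print.pc_perm_test <- function(x, ...) {
  k <- sum(x$significant)
  cat(sprintf("PC permutation test: %d significant component(s) (obs > null 95th pct)\n",
              k))
  invisible(x)
}

#' Fraction of covariance captured by a subspace
#'
#' Projects a covariance matrix into the subspace spanned by `k` orthonormal
#' basis maps and reports `trace(P^T C P) / trace(C)` -- the fraction of
#' total variance falling inside the subspace. Equals the cumulative
#' variance fraction when the basis is the covariance's own leading
#' eigenvectors.
#'
#' @param C_model N x N covariance matrix.
#' @param P_basis N x k matrix with orthonormal columns.
#' @return Scalar in `[0, 1]`.
#' @export
subspace_variance_fraction <- function(C_model, P_basis) {
  C_model <- as.matrix(C_model)
  P_basis <- as.matrix(P_basis)
  gram <- crossprod(P_basis)
  if (max(abs(gram - diag(ncol(P_basis)))) > 1e-8)
    stop("basis columns must be orthonormal")
  sum(diag(crossprod(P_basis, C_model %*% P_basis))) / sum(diag(C_model))
}

#' Experiential regression maps
#'
#' For every (parcel, score dimension) pair, the ordinary least-squares
#' regression across subjects of the score change (target) on the parcel's
#' change in GBC (predictor): `score_d = alpha_id + beta_id * dGBC_i`. The
#' aggregated slopes form one brain map per experiential dimension,
#' describing the pattern of GBC change that predicts that experiential
#' change.
#'
#' @param dgbc M x N matrix of subject change-in-GBC maps.
#' @param scores M x K matrix of subject score changes (K experiential
#'   dimensions; columns named if possible).
#' @return Object of class `regression_maps`: `beta` (N x K slopes),
#'   `alpha` (N x K intercepts), `dimensions`. Zero-variance parcels yield
#'   missing coefficients with a warning.
#' @export
experiential_regression_maps <- function(dgbc, scores) {
  dgbc <- as.matrix(dgbc); scores <- as.matrix(scores)
  M <- nrow(dgbc)
  if (M < 3L) stop("need at least three subjects")
  if (nrow(scores) != M) stop("subject count mismatch")
  K <- ncol(scores)
  dims <- colnames(scores) %||% paste0("dim", seq_len(K))
  v <- apply(dgbc, 2L, stats::var)
  zero_var <- v == 0
  if (any(zero_var))
    warning(sum(zero_var), " constant-predictor parcel(s); coefficients set missing")
  # beta = cov(dGBC_i, s_d) / var(dGBC_i); alpha from the means
  cv <- stats::cov(dgbc, scores)                    # N x K
  beta <- cv / ifelse(zero_var, NA_real_, v)
  alpha <- matrix(colMeans(scores), ncol(dgbc), K, byrow = TRUE) -
    beta * colMeans(dgbc)
  parcels <- colnames(dgbc) %||% paste0("p", seq_len(ncol(dgbc)))
  dimnames(beta) <- dimnames(alpha) <- list(parcels, dims)
  structure(list(beta = beta, alpha = alpha, dimensions = dims),
            class = "regression_maps")
}

#' @export
print.regression_maps <- function(x, ...) {
  cat(sprintf("Experiential regression maps: %d parcels x %d dimensions\n",
              nrow(x$beta), ncol(x$beta)))
  cat("  dimensions:", paste(x$dimensions, collapse = ", "), "\n")
  invisible(x)
}
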