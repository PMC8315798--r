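#' Synthetic distance-decay connectome
#'
#' Generates a structural connectome that emulates the gross statistics of
#' tractography-derived cortical connectivity: nodes are placed uniformly on
#' a two-dimensional cortical sheet, connection weights decay exponentially
#' with Euclidean distance with multiplicative lognormal jitter, the matrix
#' is symmetrized, the diagonal zeroed, and rows normalized to sum to one.
#' The Euclidean distances are returned as the connectome's distance matrix.
#'
#' @param n_nodes number of parcels (>= 5).
#' @param seed RNG seed.
#' @param sheet_size side length of the square sheet (mm).
#' @param decay_length exponential decay length of connection weight with
#'   distance (mm).
#' @param jitter_sdlog standard deviation of the lognormal weight jitter
#'   (log scale).
#' @return A [dmf_connectome()] with distances.
#' @export
make_connectome <- function(n_nodes = 30, seed = 1, sheet_size = 100,
                            decay_length = 30, jitter_sdlog = 0.5) {
  if (n_nodes < 5) stop("need at least 5 nodes")
  set.seed(seed)
  xy <- matrix(stats::runif(2 * n_nodes, 0, sheet_size), n_nodes, 2)
  D <- as.matrix(stats::dist(xy))
  W <- exp(-D / decay_length) *
    matrix(stats::rlnorm(n_nodes^2, 0, jitter_sdlog), n_nodes)
  W <- (W + t(W)) / 2
  labels <- paste0("p", seq_len(n_nodes))
  dimnames(W) <- dimnames(D) <- list(labels, labels)
  dmf_connectome(W, labels = labels, D = D, normalize = TRUE)
}

#' Synthetic spatially autocorrelated expression map
#'
#' Draws a Gaussian random field over the parcels with covariance
#' `exp(-D / autocorr_length)`, z-scores it, and maps it through the
#' standard-normal cumulative distribution, yielding values strictly in
#' (0, 1) -- the same bounded, monotone linearization applied to empirical
#' receptor-expression maps before they modulate gain.
#'
#' @param D inter-parcel distance matrix (or a `dmf_connectome` with
#'   distances).
#' @param autocorr_length spatial autocorrelation length (mm). Near zero
#'   gives an uncorrelated field.
#' @param seed RNG seed.
#' @return A [brain_map()] with values in (0, 1).
#' @export
make_expression_map <- function(D, autocorr_length = 30, seed = 1) {
  if (inherits(D, "dmf_connectome")) {
    labels <- D$labels
    D <- D$D
  } else {
    D <- as.matrix(D)
    labels <- rownames(D) %||% paste0("p", seq_len(nrow(D)))
  }
  if (is.null(D)) stop("distance matrix required")
  n <- nrow(D)
  set.seed(seed)
  K <- exp(-D / max(autocorr_length, 1e-12)) + diag(1e-8, n)
  L <- chol(K)
  z <- drop(t(L) %*% stats::rnorm(n))
  z <- (z - mean(z)) / stats::sd(z)
  brain_map(stats::pnorm(z), labels)
}

#' Synthetic subject cohort with a shared group pattern
#'
#' Emulates a within-subject pharmacological cohort: each subject's
#' change-in-GBC map is a subject-specific scaling of a shared group
#' pattern, plus low-rank individual variation, plus i.i.d. noise. Score
#' changes on `n_scores` experiential dimensions are linear in the subject
#' maps through known coupling maps `A`, plus noise -- so recovery
#' experiments have a ground truth.
#'
#' @param group_map shared group pattern (`brain_map` or numeric vector).
#' @param n_subjects cohort size (default 24).
#' @param n_scores number of experiential dimensions (default 5).
#' @param group_strength_sd s.d. of the subject-specific scaling of the
#'   group pattern (mean 1).
#' @param rank rank of the individual-variation component.
#' @param indiv_sd s.d. of individual-variation loadings.
#' @param noise_sd s.d. of i.i.d. map noise.
#' @param score_noise_sd s.d. of score noise.
#' @param seed RNG seed.
#' @return List: `dgbc` (subjects x parcels), `scores` (subjects x
#'   dimensions), `A` (parcels x dimensions coupling), `group_strength`,
#'   `indiv_patterns`, `seed`.
#' @export
make_cohort <- function(group_map, n_subjects = 24, n_scores = 5,
                        group_strength_sd = 0.3, rank = 3, indiv_sd = 0.1,
                        noise_sd = 0.05, score_noise_sd = 0.1, seed = 1) {
  g <- if (inherits(group_map, "brain_map")) unname(group_map$values) else
    as.numeric(group_map)
  labels <- if (inherits(group_map, "brain_map")) group_map$labels else
    paste0("p", seq_along(g))
  n <- length(g)
  set.seed(seed)
  strength <- 1 + stats::rnorm(n_subjects, 0, group_strength_sd)
  maps <- outer(strength, g)
  indiv_patterns <- NULL
  if (rank > 0) {
    # mutually orthogonal patterns, orthogonal to the group pattern, so the
    # planted subspace is identifiable
    raw <- cbind(g, matrix(stats::rnorm(rank * n), n, rank))
    ortho <- qr.Q(qr(raw))[, -1, drop = FALSE]
    indiv_patterns <- t(ortho) * sqrt(n) * stats::sd(g)
    loadings <- matrix(stats::rnorm(n_subjects * rank, 0, indiv_sd),
                       n_subjects, rank)
    maps <- maps + loadings %*% indiv_patterns
  }
  if (noise_sd > 0)
    maps <- maps + matrix(stats::rnorm(n_subjects * n, 0, noise_sd),
                          n_subjects, n)
  # score-coupling maps: first dimension aligned with the group pattern,
  # the rest random smooth-ish combinations
  A <- matrix(stats::rnorm(n * n_scores, 0, 0.5 / sqrt(n)), n, n_scores)
  A[, 1] <- g / sqrt(sum(g^2))
  scores <- maps %*% A +
    matrix(stats::rnorm(n_subjects * n_scores, 0, score_noise_sd),
           n_subjects, n_scores)
  dims <- c("disembodiment", "imagery", "meaning", "bliss", "spiritual")
  dims <- if (n_scores <= 5) dims[seq_len(n_scores)] else
    c(dims, paste0("dim", 6:n_scores))
  colnames(scores) <- colnames(A) <- dims
  colnames(maps) <- labels
  rownames(A) <- labels
  list(dgbc = maps, scores = scores, A = A, group_strength = strength,
       indiv_patterns = indiv_patterns, seed = seed)
}
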