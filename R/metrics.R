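#' Covariance to functional connectivity (Pearson correlation)
#'
#' @param cov_mat symmetric covariance matrix with positive diagonal.
#' @return Correlation matrix with unit diagonal.
#' @export
cov_to_fc <- function(cov_mat) {
  cov_mat <- as.matrix(cov_mat)
  d <- diag(cov_mat)
  if (any(d <= 0)) stop("zero or negative variance; cannot form correlations")
  fc <- cov_mat / sqrt(outer(d, d))
  diag(fc) <- 1
  fc
}

#' Global brain connectivity map
#'
#' Per-parcel mean of Fisher r-to-Z transformed off-diagonal correlations:
#' `GBC_i = mean_{j != i} atanh(r_ij)`. Correlation magnitudes are clipped at
#' `1 - 1e-12` before the transform.
#'
#' @param fc square correlation matrix (labels taken from dimnames).
#' @return A [brain_map()] of GBC values (Fisher Z units).
#' @export
gbc <- function(fc) {
  fc <- as.matrix(fc)
  n <- nrow(fc)
  if (n < 2L) stop("GBC needs at least two parcels")
  z <- atanh(pmin(pmax(fc, -1 + 1e-12), 1 - 1e-12))
  diag(z) <- 0
  vals <- rowSums(z) / (n - 1)
  brain_map(vals, rownames(fc))
}

#' Difference of two GBC maps (perturbed minus baseline)
#'
#' @param perturbed,baseline `brain_map`s with matching label sets.
#' @return A `brain_map` of elementwise differences, in the perturbed map's
#'   label order.
#' @export
delta_gbc <- function(perturbed, baseline) {
  stopifnot(inherits(perturbed, "brain_map"), inherits(baseline, "brain_map"))
  if (!setequal(perturbed$labels, baseline$labels))
    stop("label sets do not match")
  b <- align_map(baseline, perturbed$labels)
  brain_map(perturbed$values - b$values, perturbed$labels)
}

#' Model-empirical loading
#'
#' Projection of a model map onto an empirical map:
#' `<m, e> / <e, e>` -- the dot product of the two maps divided by the
#' squared norm of the empirical map. Sensitive to both topography and
#' magnitude; equals 1 when the maps are identical.
#'
#' @param model_map,empirical_map `brain_map`s (or plain numeric vectors of
#'   equal length).
#' @return Scalar loading.
#' @export
loading <- function(model_map, empirical_map) {
  m <- if (inherits(model_map, "brain_map")) model_map else brain_map(model_map)
  e <- if (inherits(empirical_map, "brain_map")) empirical_map else
    brain_map(empirical_map)
  if (inherits(model_map, "brain_map") && inherits(empirical_map, "brain_map")) {
    e <- align_map(e, m$labels)
  }
  ev <- unname(e$values); mv <- unname(m$values)
  if (length(ev) != length(mv)) stop("map length mismatch")
  denom <- sum(ev^2)
  if (denom == 0) stop("empirical map is all zeros")
  sum(mv * ev) / denom
}

#' Relative excitatory-to-inhibitory firing rate ratio
#'
#' The E/I ratio of a steady state is the mean excitatory firing rate across
#' nodes divided by the mean inhibitory firing rate. This function returns
#' the perturbed model's E/I ratio relative to the baseline's,
#' `(mean(r_E') / mean(r_I')) / (mean(r_E) / mean(r_I))`; 1 means no change.
#'
#' @param perturbed,baseline `steady_state` objects.
#' @return Scalar relative E/I ratio.
#' @export
ei_ratio <- function(perturbed, baseline) {
  for (s in list(perturbed, baseline)) {
    if (mean(s$r_I) == 0) stop("zero mean inhibitory rate")
  }
  (mean(perturbed$r_E) / mean(perturbed$r_I)) /
    (mean(baseline$r_E) / mean(baseline$r_I))
}

#' Spearman rank correlation
#'
#' Pearson correlation of average-tied ranks, via [stats::cor()].
#'
#' @param x,y numeric vectors of equal length (>= 3).
#' @return Scalar rank correlation.
#' @export
spearman <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) < 3L) stop("need at least three observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("constant vector; rank correlation undefined")
  stats::cor(x, y, method = "spearman")
}

# Upper-triangle Spearman correlation between two square matrices.
fc_similarity <- function(fc_model, fc_target) {
  ut <- upper.tri(fc_model)
  spearman(fc_model[ut], fc_target[ut])
}
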