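#' Calibrate the global coupling parameter by grid search
#'
#' One-dimensional grid search over the global coupling `G`. At each grid
#' value, feedback inhibition control is re-run (the tuned weights depend on
#' `G`), the fixed point is solved, the linearized BOLD covariance is
#' computed, optionally GS-regressed, converted to correlations, and scored
#' by the Spearman rank correlation between the upper-triangular elements of
#' the model and target FC matrices. Grid values where the system is
#' unstable are recorded as missing and skipped.
#'
#' @param sc a [dmf_connectome()].
#' @param params a [dmf_params()]; its `G` is ignored in favor of the grid.
#' @param target_fc target correlation matrix (same parcels as `sc`).
#' @param grid numeric grid of coupling values (default 0.01 to 0.85 in
#'   steps of 0.01).
#' @param gsr apply analytic global signal regression to the model
#'   covariance before correlation (default `TRUE`); use the same convention
#'   as the target.
#' @param hp a [hemo_params()].
#' @return Object of class `g_calibration`: `grid`, `objective`, `G_opt`,
#'   `value`.
#' @export
calibrate_g <- function(sc, params = dmf_params(), target_fc,
                        grid = seq(0.01, 0.85, by = 0.01), gsr = TRUE,
                        hp = hemo_params()) {
  target_fc <- as.matrix(target_fc)
  if (!all(dim(target_fc) == sc$n)) stop("target FC dimension mismatch")
  objective <- rep(NA_real_, length(grid))
  for (k in seq_along(grid)) {
    p_k <- override_params(params, list(G = grid[k]))
    objective[k] <- tryCatch({
      model <- dmf_model(sc, p_k, hp)
      fc_similarity(model_fc(model, NULL, gsr = gsr), target_fc)
    }, error = function(e) NA_real_)
  }
  if (all(is.na(objective)))
    stop("system unstable at every grid point")
  best <- which.max(objective)   # first maximum = smallest G on ties
  structure(list(grid = grid, objective = objective,
                 G_opt = grid[best], value = objective[best], gsr = gsr),
            class = "g_calibration")
}

#' @export
print.g_calibration <- function(x, ...) {
  cat(sprintf(
    "Global coupling calibration: %d grid points (%d unstable)\n",
    length(x$grid), sum(is.na(x$objective))))
  cat(sprintf("  best G = %g (Spearman rho = %.4f)\n", x$G_opt, x$value))
  invisible(x)
}

#' @export
coef.g_calibration <- function(object, ...) c(G = object$G_opt)

#' @export
plot.g_calibration <- function(x, ...) {
  graphics::plot(x$grid, x$objective, type = "l", xlab = "global coupling G",
                 ylab = "Spearman rank correlation", ...)
  graphics::abline(v = x$G_opt, lty = 2)
  invisible(x)
}

# Evaluate the gain-modulation pipeline over a (delta_E, delta_I) grid once:
# per cell, re-solve the perturbed fixed point with frozen FIC weights,
# compute the (optionally GS-regressed) BOLD FC, GBC, and the change-in-GBC
# map against the frozen baseline, plus the relative E/I firing-rate ratio.
sweep_gain_maps <- function(model, h, grid_E = seq(0, 0.03, by = 0.003),
                            grid_I = grid_E, gsr = TRUE) {
  if (inherits(h, "brain_map")) h <- align_map(h, model$sc$labels)$values
  n <- model$sc$n
  baseline_gbc <- model_gbc(model, NULL, gsr)
  cells <- expand.grid(delta_E = grid_E, delta_I = grid_I,
                       KEEP.OUT.ATTRS = FALSE)
  dgbc <- matrix(NA_real_, nrow(cells), n,
                 dimnames = list(NULL, model$sc$labels))
  ei <- rep(NA_real_, nrow(cells))
  for (k in seq_len(nrow(cells))) {
    mod <- gain_mod(h, cells$delta_E[k], cells$delta_I[k])
    ok <- tryCatch({
      ss <- model_steady_state(model, mod)
      gains <- modulate_gain(model$params, mod, n)
      cv <- model_covariance(model$sc, model$params, gains, model$w_EI,
                             model$hp, gsr = gsr, ss = ss)
      g <- gbc(cov_to_fc(cv$P_BOLD))
      dgbc[k, ] <- delta_gbc(g, baseline_gbc)$values
      ei[k] <- ei_ratio(ss, model$baseline)
      TRUE
    }, error = function(e) FALSE)
    if (!ok) next
  }
  list(cells = cells, dgbc = dgbc, ei_ratio = ei, grid_E = grid_E,
       grid_I = grid_I, baseline_gbc = baseline_gbc, gsr = gsr)
}

# Argmax over sweep cells with deterministic tie-breaking: among equal
# objectives, the smallest (delta_I, delta_E) in lexicographic order wins.
.sweep_argmax <- function(cells, objective) {
  if (all(is.na(objective))) stop("system unstable at every grid cell")
  best_val <- max(objective, na.rm = TRUE)
  tied <- which(!is.na(objective) & objective == best_val)
  tied <- tied[order(cells$delta_I[tied], cells$delta_E[tied])]
  tied[1]
}

#' Grid search over the gain-modulation parameters
#'
#' Two-dimensional grid search over the excitatory and inhibitory gain
#' modulation strengths `(delta_E, delta_I)`, scoring each cell by the
#' loading of the model change-in-GBC map onto an empirical target map.
#' The FIC weights and the baseline GBC map are frozen from the unperturbed
#' model. Cells where the perturbed system is unstable are recorded as
#' missing. Ties are broken toward the smallest `(delta_I, delta_E)`.
#'
#' @param model a [dmf_model()] (global coupling already calibrated).
#' @param h per-node gain-modulation weight map in `[0, 1]` (numeric vector
#'   or `brain_map`), typically a linearized receptor-expression map.
#' @param empirical_dgbc target change-in-GBC map (`brain_map` or numeric).
#' @param grid_E,grid_I modulation-strength grids (default 0 to 0.03 in
#'   steps of 0.003, giving an 11 x 11 surface).
#' @param gsr apply analytic GSR in the model pipeline (default `TRUE`).
#' @param maps optional precomputed [sweep_gain_maps()] result, reused when
#'   fitting many targets on the same model.
#' @return Object of class `gain_sweep`: grids, `surface` (loading, rows =
#'   `delta_E`, cols = `delta_I`), `ei_surface`, argmax `delta_E`/`delta_I`,
#'   `value`, best-cell `dgbc` map, `baseline_gbc`.
#' @export
sweep_gain <- function(model, h, empirical_dgbc,
                       grid_E = seq(0, 0.03, by = 0.003), grid_I = grid_E,
                       gsr = TRUE, maps = NULL) {
  if (is.null(maps)) maps <- sweep_gain_maps(model, h, grid_E, grid_I, gsr)
  target <- if (inherits(empirical_dgbc, "brain_map"))
    align_map(empirical_dgbc, model$sc$labels)$values else
      as.numeric(empirical_dgbc)
  if (length(target) != model$sc$n) stop("target map length mismatch")
  if (all(target == 0)) stop("empirical map is all zeros")
  denom <- sum(target^2)
  objective <- as.numeric(maps$dgbc %*% target) / denom
  objective[is.na(maps$dgbc[, 1])] <- NA_real_
  best <- .sweep_argmax(maps$cells, objective)
  shape <- c(length(maps$grid_E), length(maps$grid_I))
  dn <- list(delta_E = maps$grid_E, delta_I = maps$grid_I)
  structure(list(
    grid_E = maps$grid_E, grid_I = maps$grid_I,
    surface = matrix(objective, shape[1], shape[2], dimnames = dn),
    ei_surface = matrix(maps$ei_ratio, shape[1], shape[2], dimnames = dn),
    delta_E = maps$cells$delta_E[best], delta_I = maps$cells$delta_I[best],
    value = objective[best],
    dgbc = brain_map(maps$dgbc[best, ], model$sc$labels),
    baseline_gbc = maps$baseline_gbc, gsr = maps$gsr),
    class = "gain_sweep")
}

#' @export
print.gain_sweep <- function(x, ...) {
  cat(sprintf("Gain-modulation grid search: %d x %d cells (%d unstable)\n",
              length(x$grid_E), length(x$grid_I), sum(is.na(x$surface))))
  cat(sprintf("  best (delta_E, delta_I) = (%g, %g), loading = %.4f\n",
              x$delta_E, x$delta_I, x$value))
  invisible(x)
}

#' @export
coef.gain_sweep <- function(object, ...) {
  c(delta_E = object$delta_E, delta_I = object$delta_I)
}

#' @export
plot.gain_sweep <- function(x, ...) {
  graphics::image(x$grid_E, x$grid_I, x$surface,
                  xlab = expression(delta[E]), ylab = expression(delta[I]),
                  main = "model-empirical loading", ...)
  graphics::points(x$delta_E, x$delta_I, pch = 8)
  invisible(x)
}

#' @export
predict.gain_sweep <- function(object, ...) object$dgbc

#' Fit the gain-modulation parameters to individual subjects
#'
#' Repeats the two-dimensional gain grid search for each subject, using that
#' subject's change-in-GBC map as the target, and returns per-subject best
#' parameters with the corresponding model maps. The expensive model sweep
#' is computed once and shared across subjects, since the model maps do not
#' depend on the target.
#'
#' @inheritParams sweep_gain
#' @param subject_dgbc an M x N matrix of subject target maps (columns in
#'   connectome label order, or labeled), or a list of `brain_map`s.
#' @return Object of class `subject_fits`: data frame `fits` with columns
#'   `subject`, `delta_E`, `delta_I`, `loading`; matrix `dgbc` (M x N) of
#'   fitted model maps; the shared `maps` sweep.
#' @export
fit_subjects <- function(model, h, subject_dgbc,
                         grid_E = seq(0, 0.03, by = 0.003), grid_I = grid_E,
                         gsr = TRUE, maps = NULL) {
  if (is.list(subject_dgbc) && !is.matrix(subject_dgbc)) {
    subject_dgbc <- do.call(rbind, lapply(subject_dgbc, function(m)
      align_map(m, model$sc$labels)$values))
  }
  subject_dgbc <- as.matrix(subject_dgbc)
  if (!is.null(colnames(subject_dgbc)))
    subject_dgbc <- subject_dgbc[, model$sc$labels, drop = FALSE]
  if (ncol(subject_dgbc) != model$sc$n) stop("subject map length mismatch")
  if (is.null(maps)) maps <- sweep_gain_maps(model, h, grid_E, grid_I, gsr)
  M <- nrow(subject_dgbc)
  fits <- data.frame(subject = seq_len(M), delta_E = NA_real_,
                     delta_I = NA_real_, loading = NA_real_)
  model_maps <- matrix(NA_real_, M, model$sc$n,
                       dimnames = list(rownames(subject_dgbc),
                                       model$sc$labels))
  for (s in seq_len(M)) {
    fit_s <- sweep_gain(model, h, subject_dgbc[s, ], maps = maps)
    fits$delta_E[s] <- fit_s$delta_E
    fits$delta_I[s] <- fit_s$delta_I
    fits$loading[s] <- fit_s$value
    model_maps[s, ] <- fit_s$dgbc$values
  }
  structure(list(fits = fits, dgbc = model_maps, maps = maps),
            class = "subject_fits")
}

#' @export
print.subject_fits <- function(x, ...) {
  cat(sprintf("Subject-level gain fits: %d subjects\n", nrow(x$fits)))
  print(utils::head(x$fits, 10))
  if (nrow(x$fits) > 10) cat("  ...\n")
  invisible(x)
}

#' @export
coef.subject_fits <- function(object, ...) {
  as.matrix(object$fits[, c("delta_E", "delta_I")])
}
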