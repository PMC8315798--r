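#' Construct a gain-modulated dynamic mean-field network model
#'
#' Binds a structural connectome to a parameter set, runs feedback inhibition
#' control (per-node tuning of the inhibitory-to-excitatory weight so that
#' baseline excitatory rates equal `r_target`), and solves the baseline fixed
#' point. The returned object is the operating model that all analyses
#' (covariance, GBC, grid searches, surrogate tests) start from. FIC weights
#' are computed once, before any gain modulation, and frozen.
#'
#' @param sc a [dmf_connectome()].
#' @param params a [dmf_params()]; `params$G` sets the global coupling.
#' @param hp a [hemo_params()].
#' @param fic run feedback inhibition control (default `TRUE`); if `FALSE`
#'   the uniform `params$w_EI` is used at every node.
#' @param r_target FIC target excitatory rate (Hz).
#' @return Object of class `dmf_model` with elements `sc`, `params`, `hp`,
#'   `w_EI`, `baseline` (a `steady_state`), `r_target`.
#' @examples
#' sc <- make_connectome(n_nodes = 10, seed = 1)
#' m <- dmf_model(sc, dmf_params(G = 0.3))
#' range(m$baseline$r_E)
#' @export
dmf_model <- function(sc, params = dmf_params(), hp = hemo_params(),
                      fic = TRUE, r_target = 3) {
  stopifnot(inherits(sc, "dmf_connectome"), inherits(params, "dmf_params"))
  w_EI <- if (fic) apply_fic(sc, params, r_target) else
    rep(params$w_EI, sc$n)
  baseline <- solve_fixed_point(sc, params, w_EI = w_EI)
  structure(list(sc = sc, params = params, hp = hp, w_EI = w_EI,
                 baseline = baseline, r_target = r_target, fic = fic),
            class = "dmf_model")
}

#' @export
print.dmf_model <- function(x, ...) {
  cat(sprintf("Dynamic mean-field model: %d nodes, G = %g%s\n",
              x$sc$n, x$params$G,
              if (x$fic) sprintf(", FIC target %g Hz", x$r_target) else ""))
  cat(sprintf("  baseline r_E in [%.4f, %.4f] Hz, stable: %s\n",
              min(x$baseline$r_E), max(x$baseline$r_E), x$baseline$stable))
  invisible(x)
}

#' @export
summary.dmf_model <- function(object, ...) {
  x <- object
  cat("Gain-modulated dynamic mean-field network model\n\n")
  print(x$sc)
  print(x$params)
  cat(sprintf("FIC: %s (target %g Hz); w_EI in [%.4f, %.4f] nA\n",
              if (x$fic) "on" else "off", x$r_target,
              min(x$w_EI), max(x$w_EI)))
  print(x$baseline)
  invisible(x)
}

#' Steady state of a model under gain modulation
#'
#' Re-solves the fixed point with modulated gain constants, keeping the
#' FIC-tuned inhibitory weights frozen at their baseline values.
#'
#' @param model a [dmf_model()].
#' @param mod a [gain_mod()] or `NULL` for the baseline.
#' @return A `steady_state`.
#' @export
model_steady_state <- function(model, mod = NULL) {
  if (is.null(mod)) return(model$baseline)
  gains <- modulate_gain(model$params, mod, model$sc$n)
  solve_fixed_point(model$sc, model$params, gains, model$w_EI,
                    init = list(S_E = model$baseline$S_E,
                                S_I = model$baseline$S_I))
}

#' BOLD functional connectivity of a model
#'
#' Fixed point, linearized BOLD covariance, optional analytic global signal
#' regression, then conversion to Pearson correlations.
#'
#' @param model a [dmf_model()].
#' @param mod optional [gain_mod()].
#' @param gsr apply analytic GSR to the BOLD covariance (default `TRUE`).
#' @return Correlation matrix (parcel labels as dimnames).
#' @export
model_fc <- function(model, mod = NULL, gsr = TRUE) {
  gains <- modulate_gain(model$params, mod, model$sc$n)
  ss <- model_steady_state(model, mod)
  cv <- model_covariance(model$sc, model$params, gains, model$w_EI,
                         model$hp, gsr = gsr, ss = ss)
  cov_to_fc(cv$P_BOLD)
}

#' GBC map of a model
#'
#' @inheritParams model_fc
#' @return A [brain_map()] of GBC values.
#' @export
model_gbc <- function(model, mod = NULL, gsr = TRUE) {
  gbc(model_fc(model, mod, gsr))
}

#' Model change-in-GBC map under gain modulation
#'
#' GBC of the gain-modulated model minus GBC of the unperturbed model,
#' both computed through the same pipeline (including GSR if requested).
#'
#' @inheritParams model_fc
#' @param baseline_gbc optional precomputed baseline GBC map (reused across
#'   a grid sweep).
#' @return A `brain_map` of GBC differences (Fisher Z units).
#' @export
model_dgbc <- function(model, mod, gsr = TRUE, baseline_gbc = NULL) {
  if (is.null(baseline_gbc)) baseline_gbc <- model_gbc(model, NULL, gsr)
  delta_gbc(model_gbc(model, mod, gsr), baseline_gbc)
}

#' Simulate the full nonlinear model (Euler-Maruyama)
#'
#' Forward-integrates the coupled synaptic and hemodynamic equations with
#' Gaussian noise on both gating variables (standard deviation
#' `sigma * sqrt(dt)` per step), starting from the fixed point. The
#' excitatory gating is clamped to `[0, 1]`, the inhibitory gating at 0.
#' BOLD is read out through the observation equation and sampled every
#' `tr` seconds after discarding `burn_in` seconds.
#'
#' @param object a [dmf_model()].
#' @param nsim simulated duration T (s).
#' @param seed RNG seed (integer) or `NULL` to use the current RNG state.
#' @param mod optional [gain_mod()].
#' @param dt integrator step (s), at most 0.001.
#' @param tr BOLD sampling interval (s).
#' @param burn_in discarded initial duration (s).
#' @param keep_synaptic also return the sampled gating variables.
#' @param ... unused.
#' @return List with `bold` (samples x nodes matrix), `time`, and optionally
#'   `S_E`, `S_I`.
#' @export
simulate.dmf_model <- function(object, nsim = 1000, seed = NULL, mod = NULL,
                               dt = 1e-3, tr = 1, burn_in = 10,
                               keep_synaptic = FALSE, ...) {
  model <- object
  gains <- modulate_gain(model$params, mod, model$sc$n)
  ss <- model_steady_state(model, mod)
  .sde_run(model$sc, model$params, gains, model$w_EI, model$hp, ss,
           T_total = nsim, dt = dt, seed = seed, tr = tr,
           burn_in = burn_in, keep_synaptic = keep_synaptic)
}

# Shared Euler-Maruyama driver around the compiled integrator.
.sde_run <- function(sc, params, gains, w_EI, hp, ss, T_total, dt, seed,
                     tr, burn_in, keep_synaptic) {
  if (dt > 1e-3 + 1e-15) stop("dt must be at most 1 ms")
  if (!is.null(seed)) set.seed(seed)
  hss <- hemo_steady_state(ss$S_E, hp)
  p <- params
  out <- sde_integrate_cpp(
    C = sc$C, w_EI = w_EI,
    a_E = gains$a_E, a_I = gains$a_I,
    Ib = p$Ib, J = p$J, gamma_kin = p$gamma_kin,
    W_E = p$W_E, W_I = p$W_I, w_EE = p$w_EE, w_IE = p$w_IE,
    tau_E = p$tau_E, tau_I = p$tau_I,
    b_E = p$b_E, d_E = p$d_E, b_I = p$b_I, d_I = p$d_I,
    G = p$G, sigma = p$sigma,
    rho = hp$rho, tau_h = hp$tau_h, kappa = hp$kappa,
    gamma_h = hp$gamma_h, alpha = hp$alpha, V0 = hp$V0,
    k1 = hp$k1, k2 = hp$k2, k3 = hp$k3,
    S_E0 = ss$S_E, S_I0 = ss$S_I,
    x0 = hss$x, f0 = hss$f, v0 = hss$v, q0 = hss$q,
    T_total = T_total, dt = dt, tr = tr, burn_in = burn_in,
    keep_synaptic = keep_synaptic)
  colnames(out$bold) <- sc$labels
  out$time <- burn_in + tr * seq_len(nrow(out$bold))
  if (!keep_synaptic) out$S_E <- out$S_I <- NULL
  out
}

#' Low-level SDE simulation of the synaptic-hemodynamic system
#'
#' Functional interface to the Euler-Maruyama integrator used by
#' [simulate.dmf_model()], for callers that work with raw components rather
#' than a fitted model object.
#'
#' @inheritParams drift
#' @param hp a [hemo_params()].
#' @param T_total simulated duration (s).
#' @param dt time step (s), at most 0.001.
#' @param seed RNG seed or `NULL`.
#' @param tr BOLD sampling interval (s).
#' @param burn_in discarded initial duration (s).
#' @param keep_synaptic return gating time series as well.
#' @param init optional list with starting `S_E`, `S_I` gating vectors;
#'   default is the solved fixed point.
#' @return As [simulate.dmf_model()].
#' @export
simulate_sde <- function(sc, params, gains = NULL, w_EI = NULL,
                         hp = hemo_params(), T_total = 1000, dt = 1e-3,
                         seed = NULL, tr = 1, burn_in = 10,
                         keep_synaptic = FALSE, init = NULL) {
  n <- sc$n
  if (is.null(gains)) gains <- modulate_gain(params, NULL, n)
  if (is.null(w_EI)) w_EI <- rep(params$w_EI, n)
  if (length(w_EI) == 1L) w_EI <- rep(w_EI, n)
  ss <- if (!is.null(init)) list(S_E = init$S_E, S_I = init$S_I) else {
    fp <- solve_fixed_point(sc, params, gains, w_EI)
    if (!isTRUE(fp$stable)) stop("operating point unstable; refuse to simulate")
    fp
  }
  .sde_run(sc, params, gains, w_EI, hp, ss, T_total = T_total, dt = dt,
           seed = seed, tr = tr, burn_in = burn_in,
           keep_synaptic = keep_synaptic)
}
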