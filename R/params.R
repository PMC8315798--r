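#' Synaptic model parameters
#'
#' Constructs the full set of fixed parameters of the two-population dynamic
#' mean-field model. Defaults are the standard values for the reduced
#' excitatory-inhibitory mean-field reduction of a spiking network: background
#' current `Ib`, NMDA conductance `J`, kinetic parameter `gamma_kin`,
#' background-input scalings `W_E`/`W_I`, local synaptic weights, synaptic time
#' constants, the three transfer-function constants per population, the global
#' coupling `G`, and the noise standard deviation `sigma`.
#'
#' `w_EI` is the baseline inhibitory-to-excitatory weight; it is overridden
#' per node by feedback inhibition control (see [apply_fic()]).
#'
#' @param Ib background input current (nA).
#' @param J effective NMDA conductance (nA).
#' @param gamma_kin kinetic rate parameter (dimensionless).
#' @param W_E,W_I background current scaling for the excitatory and inhibitory
#'   populations (dimensionless).
#' @param w_EE local excitatory self-coupling (nA).
#' @param w_EI baseline inhibitory-to-excitatory weight (nA); replaced
#'   per node when feedback inhibition control is applied.
#' @param w_IE excitatory-to-inhibitory weight (nA).
#' @param tau_E,tau_I synaptic time constants (s).
#' @param a_E,b_E,d_E excitatory transfer-function constants
#'   (nC^-1, Hz, s). `a_E` is the neural gain.
#' @param a_I,b_I,d_I inhibitory transfer-function constants.
#' @param G global long-range coupling (dimensionless, >= 0).
#' @param sigma standard deviation of the stochastic input noise (nA).
#' @return An object of class `dmf_params` (a named list).
#' @examples
#' p <- dmf_params(G = 0.5)
#' p$a_E
#' @export
dmf_params <- function(Ib = 0.382, J = 0.15, gamma_kin = 0.641,
                       W_E = 1.0, W_I = 0.7,
                       w_EE = 0.21, w_EI = 1.0, w_IE = 0.15,
                       tau_E = 0.1, tau_I = 0.01,
                       a_E = 310, b_E = 125, d_E = 0.16,
                       a_I = 615, b_I = 177, d_I = 0.087,
                       G = 0, sigma = 0.01) {
  p <- list(Ib = Ib, J = J, gamma_kin = gamma_kin, W_E = W_E, W_I = W_I,
            w_EE = w_EE, w_EI = w_EI, w_IE = w_IE,
            tau_E = tau_E, tau_I = tau_I,
            a_E = a_E, b_E = b_E, d_E = d_E,
            a_I = a_I, b_I = b_I, d_I = d_I,
            G = G, sigma = sigma)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a finite scalar")
  }
  if (tau_E <= 0 || tau_I <= 0) stop("time constants must be positive")
  if (a_E <= 0 || a_I <= 0 || d_E <= 0 || d_I <= 0)
    stop("transfer-function constants a and d must be positive")
  if (G < 0) stop("G must be non-negative")
  if (sigma < 0) stop("sigma must be non-negative")
  structure(p, class = "dmf_params")
}

#' @export
print.dmf_params <- function(x, ...) {
  cat("Dynamic mean-field model parameters\n")
  cat(sprintf("  G = %g, sigma = %g nA\n", x$G, x$sigma))
  cat(sprintf("  Ib = %g nA, J = %g nA, gamma = %g\n", x$Ib, x$J, x$gamma_kin))
  cat(sprintf("  E: W = %g, w_EE = %g, tau = %g s, (a, b, d) = (%g, %g, %g)\n",
              x$W_E, x$w_EE, x$tau_E, x$a_E, x$b_E, x$d_E))
  cat(sprintf("  I: W = %g, w_IE = %g, tau = %g s, (a, b, d) = (%g, %g, %g)\n",
              x$W_I, x$w_IE, x$tau_I, x$a_I, x$b_I, x$d_I))
  invisible(x)
}

#' Balloon-Windkessel hemodynamic parameters
#'
#' Parameters of the hemodynamic observation model that maps excitatory
#' synaptic gating to the BOLD signal: resting oxygen extraction fraction
#' `rho`, hemodynamic transit time `tau_h`, signal decay rate `kappa`,
#' flow-dependent elimination rate `gamma_h`, Grubb's exponent `alpha`,
#' resting venous volume fraction `V0`, and the three field-strength
#' constants `k1`-`k3` (3 T).
#'
#' @param rho resting oxygen extraction fraction, in (0, 1).
#' @param tau_h hemodynamic transit time (s).
#' @param kappa rate of vasodilatory signal decay (1/s).
#' @param gamma_h rate of flow-dependent elimination (1/s).
#' @param alpha Grubb's vessel stiffness exponent, in (0, 1).
#' @param V0 resting blood volume fraction.
#' @param k1,k2,k3 dimensionless 3 T field-strength constants.
#' @return An object of class `hemo_params`.
#' @export
hemo_params <- function(rho = 0.34, tau_h = 0.98, kappa = 0.65,
                        gamma_h = 0.41, alpha = 0.32, V0 = 0.02,
                        k1 = 3.72, k2 = 0.53, k3 = 0.53) {
  p <- list(rho = rho, tau_h = tau_h, kappa = kappa, gamma_h = gamma_h,
            alpha = alpha, V0 = V0, k1 = k1, k2 = k2, k3 = k3)
  for (nm in names(p)) {
    if (!is.numeric(p[[nm]]) || length(p[[nm]]) != 1L || !is.finite(p[[nm]]))
      stop("parameter '", nm, "' must be a finite scalar")
  }
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)")
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)")
  if (tau_h <= 0 || kappa <= 0 || gamma_h <= 0) stop("rates must be positive")
  structure(p, class = "hemo_params")
}

#' @export
print.hemo_params <- function(x, ...) {
  cat("Balloon-Windkessel hemodynamic parameters\n")
  cat(sprintf("  rho = %g, tau_h = %g s, kappa = %g /s, gamma_h = %g /s\n",
              x$rho, x$tau_h, x$kappa, x$gamma_h))
  cat(sprintf("  alpha = %g, V0 = %g, (k1, k2, k3) = (%g, %g, %g)\n",
              x$alpha, x$V0, x$k1, x$k2, x$k3))
  invisible(x)
}

#' Gain modulation specification
#'
#' Per-node modulation of the neural gain constants. Node `i` of population
#' `p` receives gain `a_i^p = (1 + h_i * delta_p) * a0^p`, where `h` is a
#' brain map of modulation weights in `[0, 1]` (typically a linearized
#' receptor-gene expression map) and `delta_E`, `delta_I` set the modulation
#' strength on the excitatory and inhibitory populations. With
#' `delta_E = delta_I = 0` the unmodulated gains are recovered exactly.
#'
#' @param h numeric vector of per-node modulation weights in `[0, 1]`, or a
#'   `brain_map`.
#' @param delta_E,delta_I modulation strengths (dimensionless).
#' @return An object of class `gain_mod`.
#' @export
gain_mod <- function(h, delta_E = 0, delta_I = 0) {
  if (inherits(h, "brain_map")) h <- h$values
  if (!is.numeric(h) || any(!is.finite(h))) stop("h must be finite numeric")
  if (any(h < 0 | h > 1)) stop("h must lie in [0, 1]")
  if (!is.finite(delta_E) || !is.finite(delta_I))
    stop("delta values must be finite")
  structure(list(h = as.numeric(h), delta_E = delta_E, delta_I = delta_I),
            class = "gain_mod")
}

#' Apply configuration overrides to a parameter set
#'
#' Overrides fields of a [dmf_params()] or [hemo_params()] object from a named
#' list, e.g. one read from a YAML or JSON configuration file. Unknown keys
#' are rejected.
#'
#' @param params a `dmf_params` or `hemo_params` object.
#' @param overrides named list of replacement values.
#' @return Parameter object of the same class with overrides applied.
#' @export
override_params <- function(params, overrides) {
  if (is.null(overrides) || length(overrides) == 0L) return(params)
  bad <- setdiff(names(overrides), names(params))
  if (length(bad))
    stop("unknown parameter key(s): ", paste(bad, collapse = ", "))
  args <- utils::modifyList(unclass(params), overrides)
  do.call(if (inherits(params, "hemo_params")) hemo_params else dmf_params,
          args)
}

#' Read a model configuration file
#'
#' Reads a YAML or JSON configuration with optional blocks `synaptic`,
#' `hemodynamic`, `gsr`, `grids`, `seed`, and `paths`. Keys inside the
#' parameter blocks must match the parameter names of [dmf_params()] /
#' [hemo_params()]; unknown keys raise an error.
#'
#' @param path path to a `.yaml`/`.yml` or `.json` file.
#' @return A named list of class `run_config`.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  cfg <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  known <- c("synaptic", "hemodynamic", "gsr", "grids", "seed", "paths",
             "out_dir")
  bad <- setdiff(names(cfg), known)
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  # validate parameter keys eagerly so typos fail at load time
  if (!is.null(cfg$synaptic)) override_params(dmf_params(), cfg$synaptic)
  if (!is.null(cfg$hemodynamic)) override_params(hemo_params(), cfg$hemodynamic)
  structure(cfg, class = "run_config")
}
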