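#' Balloon-Windkessel drift field
#'
#' Time derivatives of the four hemodynamic state variables per node: the
#' vasodilatory signal `x` driven by excitatory synaptic gating, blood inflow
#' `f`, blood volume `v`, and deoxyhemoglobin content `q`. The vasodilatory
#' signal is driven by the raw gating variable, so a nonzero synaptic
#' operating point implies a nonzero hemodynamic operating point; downstream
#' statistics use correlations and are unaffected.
#'
#' @param state list with numeric vectors `x`, `f`, `v`, `q` (one per node).
#' @param s_E excitatory synaptic gating vector.
#' @param hp a [hemo_params()] object.
#' @return List of derivative vectors `dx`, `df`, `dv`, `dq`.
#' @export
hemo_drift <- function(state, s_E, hp) {
  f <- state$f; v <- state$v; q <- state$q; x <- state$x
  if (any(f <= 0) || any(v <= 0)) stop("blood inflow and volume must be positive")
  dx <- s_E - hp$kappa * x - hp$gamma_h * (f - 1)
  df <- x
  dv <- (f - v^(1 / hp$alpha)) / hp$tau_h
  E <- 1 - (1 - hp$rho)^(1 / f)            # oxygen extraction at inflow f
  dq <- (f * E / hp$rho - q * v^(1 / hp$alpha - 1)) / hp$tau_h
  list(dx = dx, df = df, dv = dv, dq = dq)
}

#' Hemodynamic steady state for constant synaptic gating
#'
#' Closed-form fixed point of the Balloon-Windkessel equations under a
#' constant excitatory gating input: `x = 0`, `f = 1 + s_E/gamma_h`,
#' `v = f^alpha`, and `q` from the zero-derivative condition of the
#' deoxyhemoglobin equation. Used as the linearization point of the
#' hemodynamic subsystem.
#'
#' @param s_E constant excitatory gating (vector or scalar, >= 0).
#' @param hp a [hemo_params()] object.
#' @return List with vectors `x`, `f`, `v`, `q`.
#' @export
hemo_steady_state <- function(s_E, hp) {
  if (any(s_E < 0)) stop("s_E must be non-negative")
  f <- 1 + s_E / hp$gamma_h
  v <- f^hp$alpha
  E <- 1 - (1 - hp$rho)^(1 / f)
  q <- (f * E / hp$rho) / v^(1 / hp$alpha - 1)
  list(x = rep(0, length(f)), f = f, v = v, q = q)
}

#' BOLD observation equation
#'
#' Static mapping from blood volume and deoxyhemoglobin to the BOLD signal,
#' `y = V0 * (k1*(1 - q) + k2*(1 - q/v) + k3*(1 - v))`.
#'
#' @param v blood volume (dimensionless, > 0).
#' @param q deoxyhemoglobin content (dimensionless).
#' @param hp a [hemo_params()] object.
#' @return BOLD signal (dimensionless).
#' @export
bold_signal <- function(v, q, hp) {
  if (any(v <= 0)) stop("blood volume must be positive")
  hp$V0 * (hp$k1 * (1 - q) + hp$k2 * (1 - q / v) + hp$k3 * (1 - v))
}

# Partial derivatives of the BOLD equation with respect to (v, q),
# evaluated at a hemodynamic state. Used to build the BOLD readout matrix.
bold_partials <- function(v, q, hp) {
  list(dv = hp$V0 * (hp$k2 * q / v^2 - hp$k3),
       dq = hp$V0 * (-hp$k1 - hp$k2 / v))
}

# Analytic 4x4 Jacobian blocks of the hemodynamic drift for one node,
# plus the derivative of the x-equation with respect to S_E (= 1).
hemo_jacobian_node <- function(f, v, q, hp) {
  ia <- 1 / hp$alpha
  E <- 1 - (1 - hp$rho)^(1 / f)
  dE_term <- E + (1 - hp$rho)^(1 / f) * log(1 - hp$rho) / f  # d(f*E)/df
  J <- matrix(0, 4, 4)
  # state order within node: x, f, v, q
  J[1, 1] <- -hp$kappa
  J[1, 2] <- -hp$gamma_h
  J[2, 1] <- 1
  J[3, 2] <- 1 / hp$tau_h
  J[3, 3] <- -ia * v^(ia - 1) / hp$tau_h
  J[4, 2] <- dE_term / (hp$rho * hp$tau_h)
  J[4, 3] <- -q * (ia - 1) * v^(ia - 2) / hp$tau_h
  J[4, 4] <- -v^(ia - 1) / hp$tau_h
  J
}
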