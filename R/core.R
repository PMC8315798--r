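#' Population transfer function (current to firing rate)
#'
#' The input-output relation of a neuronal population,
#' `phi(I) = (a*I - b) / (1 - exp(-d*(a*I - b)))`. The function is strictly
#' positive, strictly increasing in `I`, and continuous at `a*I = b` where it
#' takes its removable-singularity limit `1/d`. The slope parameter `a` is
#' the neural gain.
#'
#' @param I synaptic current (nA); vectorized. Recycled against `a`.
#' @param a gain constant (nC^-1); scalar or per-node vector.
#' @param b threshold constant (Hz).
#' @param d curvature constant (s).
#' @return Firing rate (Hz).
#' @examples
#' transfer_rate(125 / 310, 310, 125, 0.16)  # removable singularity: 1/d
#' @export
transfer_rate <- function(I, a, b, d) {
  if (any(!is.finite(I))) stop("non-finite input current")
  if (any(a <= 0) || d <= 0) stop("a and d must be positive")
  x <- a * I - b
  u <- d * x
  r <- numeric(length(x))
  small <- abs(u) < 1e-5
  # series of u/(1-exp(-u)) about u = 0: 1 + u/2 + u^2/12
  r[small] <- (1 + u[small] / 2 + u[small]^2 / 12) / d
  pos <- !small & u >= 0
  r[pos] <- x[pos] / (1 - exp(-u[pos]))
  neg <- !small & u < 0
  eu <- exp(u[neg])                      # stable for large negative u
  r[neg] <- x[neg] * eu / (eu - 1)
  r
}

#' Slope of the transfer function with respect to current
#'
#' Analytic derivative `d phi / d I`, used in Jacobian assembly.
#'
#' @inheritParams transfer_rate
#' @return Derivative of firing rate with respect to current (Hz/nA).
#' @keywords internal
#' @export
transfer_slope <- function(I, a, b, d) {
  x <- a * I - b
  u <- d * x
  g <- numeric(length(x))
  small <- abs(u) < 1e-5
  # derivative of u/(1-exp(-u)) wrt x, expanded about u = 0
  g[small] <- 0.5 + u[small] / 6
  big <- !small
  eu <- exp(-abs(u[big]))
  # g'(x) = (1 - e^{-u} - u e^{-u}) / (1 - e^{-u})^2, computed stably
  num <- ifelse(u[big] >= 0, 1 - eu - u[big] * eu,
                eu - 1 - u[big])          # multiplied through by e^{u} for u<0
  den <- ifelse(u[big] >= 0, (1 - eu)^2, (eu - 1)^2 / eu)
  g[big] <- num / den
  a * g
}

#' Per-node gain constants under modulation
#'
#' Returns the modulated gain constants `a_i^p = (1 + h_i * delta_p) * a0^p`
#' for both populations. With `delta_E = delta_I = 0` (or `mod = NULL`) the
#' baseline constants are returned exactly.
#'
#' @param params a [dmf_params()] object.
#' @param mod a [gain_mod()] object, or `NULL` for no modulation.
#' @param n number of nodes (required when `mod` is `NULL`).
#' @return List with per-node vectors `a_E` and `a_I`.
#' @export
modulate_gain <- function(params, mod = NULL, n = NULL) {
  if (is.null(mod)) {
    if (is.null(n)) stop("n is required when mod is NULL")
    return(list(a_E = rep(params$a_E, n), a_I = rep(params$a_I, n)))
  }
  stopifnot(inherits(mod, "gain_mod"))
  a_E <- (1 + mod$h * mod$delta_E) * params$a_E
  a_I <- (1 + mod$h * mod$delta_I) * params$a_I
  if (any(a_E <= 0) || any(a_I <= 0))
    stop("gain modulation drove a gain constant non-positive")
  list(a_E = a_E, a_I = a_I)
}

# Synaptic currents of both populations (internal workhorse).
synaptic_currents <- function(S_E, S_I, sc, params, w_EI) {
  I_E <- params$W_E * params$Ib + params$w_EE * S_E +
    params$G * params$J * as.vector(sc$C %*% S_E) - w_EI * S_I
  I_I <- params$W_I * params$Ib + params$w_IE * S_E - S_I
  list(I_E = unname(I_E), I_I = unname(I_I))
}

#' Drift field of the synaptic dynamics
#'
#' Noise-free time derivatives of the excitatory and inhibitory synaptic
#' gating variables. The excitatory gating carries a saturation factor
#' `(1 - S_E)`; the inhibitory gating, as in the governing equations, does
#' not.
#'
#' @param S_E,S_I gating vectors (one entry per node).
#' @param sc a [dmf_connectome()].
#' @param params a [dmf_params()].
#' @param gains list with per-node `a_E`, `a_I` (see [modulate_gain()]);
#'   `NULL` for baseline gains.
#' @param w_EI per-node inhibitory-to-excitatory weights (nA); defaults to
#'   `params$w_EI` at every node.
#' @return List with derivative vectors `dS_E`, `dS_I` and the intermediate
#'   `I_E`, `I_I`, `r_E`, `r_I`.
#' @export
drift <- function(S_E, S_I, sc, params, gains = NULL, w_EI = NULL) {
  n <- sc$n
  if (length(S_E) != n || length(S_I) != n)
    stop("state dimension does not match connectome")
  if (is.null(gains)) gains <- modulate_gain(params, NULL, n)
  if (is.null(w_EI)) w_EI <- rep(params$w_EI, n)
  if (length(w_EI) == 1L) w_EI <- rep(w_EI, n)
  cur <- synaptic_currents(S_E, S_I, sc, params, w_EI)
  r_E <- transfer_rate(cur$I_E, gains$a_E, params$b_E, params$d_E)
  r_I <- transfer_rate(cur$I_I, gains$a_I, params$b_I, params$d_I)
  dS_E <- -S_E / params$tau_E + (1 - S_E) * params$gamma_kin * r_E
  dS_I <- -S_I / params$tau_I + r_I
  list(dS_E = dS_E, dS_I = dS_I, I_E = cur$I_E, I_I = cur$I_I,
       r_E = r_E, r_I = r_I)
}

# Analytic 2N x 2N Jacobian of the synaptic drift at (S_E, S_I).
# Ordering: the N excitatory gating variables first, then the N inhibitory.
synaptic_jacobian <- function(S_E, S_I, sc, params, gains, w_EI) {
  n <- sc$n
  cur <- synaptic_currents(S_E, S_I, sc, params, w_EI)
  r_E <- transfer_rate(cur$I_E, gains$a_E, params$b_E, params$d_E)
  sl_E <- transfer_slope(cur$I_E, gains$a_E, params$b_E, params$d_E)
  sl_I <- transfer_slope(cur$I_I, gains$a_I, params$b_I, params$d_I)
  g <- params$gamma_kin
  pre_E <- (1 - S_E) * g * sl_E
  J_EE <- diag(-1 / params$tau_E - g * r_E, n) +
    pre_E * (diag(params$w_EE, n) + params$G * params$J * sc$C)
  J_EI <- diag(-pre_E * w_EI, n)
  J_IE <- diag(sl_I * params$w_IE, n)
  J_II <- diag(-1 / params$tau_I - sl_I, n)
  rbind(cbind(J_EE, J_EI), cbind(J_IE, J_II))
}

#' Solve for the fixed point of the synaptic dynamics
#'
#' Finds the noise-free fixed point of the coupled gating equations by damped
#' Newton iteration on the 2N-dimensional drift field (analytic Jacobian),
#' with a damped pseudo-time fallback. Stability is assessed from the
#' spectrum of the synaptic Jacobian at the solution.
#'
#' @inheritParams drift
#' @param init optional list with starting `S_E`, `S_I` (default 0.1 each).
#' @param tol convergence tolerance on the maximum absolute drift.
#' @param max_iter maximum iterations.
#' @return An object of class `steady_state` with elements `S_E`, `S_I`,
#'   `r_E`, `r_I`, `I_E`, `I_I`, `stable`, `residual`.
#' @export
solve_fixed_point <- function(sc, params, gains = NULL, w_EI = NULL,
                              init = NULL, tol = 1e-12, max_iter = 10000L) {
  n <- sc$n
  if (is.null(gains)) gains <- modulate_gain(params, NULL, n)
  if (is.null(w_EI)) w_EI <- rep(params$w_EI, n)
  if (length(w_EI) == 1L) w_EI <- rep(w_EI, n)
  S_E <- if (is.null(init)) rep(0.1, n) else init$S_E
  S_I <- if (is.null(init)) rep(0.1, n) else init$S_I

  f <- drift(S_E, S_I, sc, params, gains, w_EI)
  res <- max(abs(c(f$dS_E, f$dS_I)))
  converged <- res < tol
  iter <- 0L
  while (!converged && iter < max_iter) {
    iter <- iter + 1L
    J <- synaptic_jacobian(S_E, S_I, sc, params, gains, w_EI)
    step <- tryCatch(solve(J, -c(f$dS_E, f$dS_I)), error = function(e) NULL)
    if (is.null(step)) break
    lambda <- 1
    improved <- FALSE
    for (k in 1:40) {
      S_E_new <- S_E + lambda * step[1:n]
      S_I_new <- S_I + lambda * step[(n + 1):(2 * n)]
      f_new <- drift(S_E_new, S_I_new, sc, params, gains, w_EI)
      res_new <- max(abs(c(f_new$dS_E, f_new$dS_I)))
      if (is.finite(res_new) && res_new < res) {
        S_E <- S_E_new; S_I <- S_I_new; f <- f_new; res <- res_new
        improved <- TRUE
        break
      }
      lambda <- lambda / 2
    }
    if (!improved) break
    converged <- res < tol
  }
  if (!converged) {
    # damped pseudo-time fallback
    dt <- 0.1 * min(params$tau_E, params$tau_I)
    for (iter2 in seq_len(max_iter)) {
      S_E <- S_E + dt * f$dS_E
      S_I <- pmax(S_I + dt * f$dS_I, 0)
      S_E <- pmin(pmax(S_E, 0), 1)
      f <- drift(S_E, S_I, sc, params, gains, w_EI)
      res <- max(abs(c(f$dS_E, f$dS_I)))
      if (!is.finite(res)) stop("fixed point not found (divergence)")
      if (res < tol) { converged <- TRUE; break }
    }
  }
  if (!converged) stop("fixed point not found")
  J <- synaptic_jacobian(S_E, S_I, sc, params, gains, w_EI)
  stable <- max(Re(eigen(J, only.values = TRUE)$values)) < 0
  S_E <- unname(S_E); S_I <- unname(S_I)
  structure(list(S_E = S_E, S_I = S_I, r_E = f$r_E, r_I = f$r_I,
                 I_E = f$I_E, I_I = f$I_I, stable = stable, residual = res),
            class = "steady_state")
}

#' @export
print.steady_state <- function(x, ...) {
  cat(sprintf(
    "Steady state: %d nodes, r_E in [%.3f, %.3f] Hz, r_I in [%.3f, %.3f] Hz\n",
    length(x$S_E), min(x$r_E), max(x$r_E), min(x$r_I), max(x$r_I)))
  cat(sprintf("  stable: %s, max |drift| = %.2e\n", x$stable, x$residual))
  invisible(x)
}

#' Feedback inhibition control (FIC)
#'
#' Tunes the per-node inhibitory-to-excitatory feedback weight so that the
#' unmodulated model's fixed point has excitatory firing rate `r_target`
#' (default 3 Hz) at every node. The tuning is computed before any gain
#' modulation and the resulting weights are then frozen; gain sweeps reuse
#' them.
#'
#' The procedure is closed-form up to two scalar root-finds: invert the
#' excitatory transfer function at the target rate to obtain the excitatory
#' current `I_E*`; set the excitatory gating to its rate-consistent value
#' `S_E* = gamma*r*tau_E / (1 + gamma*r*tau_E)`; solve the (node-independent)
#' inhibitory fixed-point equation `S_I = tau_I * phi_I(I_I(S_I))`; and read
#' off each node's weight from the excitatory current-balance equation.
#'
#' @inheritParams drift
#' @param r_target target excitatory firing rate (Hz).
#' @return Numeric vector of per-node weights `w_EI` (nA).
#' @export
apply_fic <- function(sc, params, r_target = 3) {
  n <- sc$n
  # invert phi_E at the target rate: scalar root in x = a*I - b
  xr <- stats::uniroot(
    function(x) transfer_rate((x + params$b_E) / params$a_E,
                              params$a_E, params$b_E, params$d_E) - r_target,
    interval = c(-2000, 2000), tol = 1e-14)$root
  I_E_star <- (xr + params$b_E) / params$a_E
  g <- params$gamma_kin
  S_E_star <- g * r_target * params$tau_E / (1 + g * r_target * params$tau_E)
  # inhibitory fixed point: same scalar equation at every node (no long-range
  # input to the I population)
  inh_res <- function(S) {
    I_I <- params$W_I * params$Ib + params$w_IE * S_E_star - S
    S - params$tau_I * transfer_rate(I_I, params$a_I, params$b_I, params$d_I)
  }
  S_I_star <- stats::uniroot(inh_res, interval = c(0, 20), tol = 1e-14)$root
  long_range <- params$G * params$J * as.vector(sc$C %*% rep(S_E_star, n))
  w_EI <- unname((params$W_E * params$Ib + params$w_EE * S_E_star +
                    long_range - I_E_star) / S_I_star)
  if (any(w_EI <= 0))
    stop("FIC produced non-positive w_EI; inhibitory feedback must be positive")
  w_EI
}
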