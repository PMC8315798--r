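#' Jacobian of the full neural-hemodynamic system
#'
#' Assembles the analytic Jacobian of the 6N-dimensional drift field at the
#' operating point defined by a synaptic steady state and the hemodynamic
#' steady state it induces. State ordering is blocked per node:
#' `(S_E, S_I, x, f, v, q)` for node 1, then node 2, and so on. Long-range
#' coupling enters only between excitatory gating variables; hemodynamics are
#' driven only by the local excitatory gating.
#'
#' @param ss a `steady_state` from [solve_fixed_point()]; must be stable.
#' @param hemo_ss hemodynamic steady state from [hemo_steady_state()]
#'   evaluated at `ss$S_E`; computed if `NULL`.
#' @inheritParams drift
#' @param hp a [hemo_params()] object.
#' @return 6N x 6N Jacobian matrix.
#' @export
build_jacobian <- function(ss, hemo_ss = NULL, sc, params, gains = NULL,
                           w_EI = NULL, hp = hemo_params()) {
  if (!isTRUE(ss$stable))
    stop("operating point is unstable; refuse to linearize")
  n <- sc$n
  if (is.null(gains)) gains <- modulate_gain(params, NULL, n)
  if (is.null(w_EI)) w_EI <- rep(params$w_EI, n)
  if (length(w_EI) == 1L) w_EI <- rep(w_EI, n)
  if (is.null(hemo_ss)) hemo_ss <- hemo_steady_state(ss$S_E, hp)

  Jsyn <- synaptic_jacobian(ss$S_E, ss$S_I, sc, params, gains, w_EI)
  m <- 6L * n
  A <- matrix(0, m, m)
  iSE <- 6L * (seq_len(n) - 1L) + 1L
  iSI <- iSE + 1L
  A[iSE, iSE] <- Jsyn[1:n, 1:n]
  A[iSE, iSI] <- Jsyn[1:n, (n + 1):(2 * n)]
  A[iSI, iSE] <- Jsyn[(n + 1):(2 * n), 1:n]
  A[iSI, iSI] <- Jsyn[(n + 1):(2 * n), (n + 1):(2 * n)]
  for (i in seq_len(n)) {
    off <- 6L * (i - 1L)
    A[off + 3L, off + 1L] <- 1  # vasodilatory signal driven by S_E
    A[off + 3:6, off + 3:6] <- hemo_jacobian_node(hemo_ss$f[i], hemo_ss$v[i],
                                                  hemo_ss$q[i], hp)
  }
  A
}

#' Noise covariance of the stochastic forcing
#'
#' Diagonal matrix with `sigma^2` on the synaptic gating rows (noise drives
#' both the excitatory and inhibitory populations) and zeros on the
#' hemodynamic rows, in the blocked per-node state ordering.
#'
#' @param n number of nodes.
#' @param sigma noise standard deviation (nA).
#' @return 6N x 6N diagonal matrix.
#' @export
noise_covariance <- function(n, sigma) {
  d <- rep(0, 6L * n)
  iSE <- 6L * (seq_len(n) - 1L) + 1L
  d[iSE] <- sigma^2
  d[iSE + 1L] <- sigma^2
  diag(d, 6L * n)
}

#' Solve the continuous Lyapunov equation
#'
#' Direct dense solve of `A P + P A^T + Q = 0` for a Hurwitz `A`, via the
#' eigendecomposition of `A`: with `A = V D V^-1` the transformed equation is
#' diagonal and divides elementwise by `d_i + conj(d_j)`. The result is
#' symmetrized and checked against the residual bound
#' `||AP + PA^T + Q||_max < 1e-8 * ||Q||_max`.
#'
#' @param A square drift matrix, all eigenvalue real parts negative.
#' @param Q symmetric positive semidefinite forcing covariance.
#' @return Symmetric state covariance matrix `P`.
#' @examples
#' solve_lyapunov(matrix(-2), matrix(1))  # scalar OU: sigma^2 / (2 theta)
#' @export
solve_lyapunov <- function(A, Q) {
  A <- as.matrix(A); Q <- as.matrix(Q)
  if (!all(dim(A) == dim(Q))) stop("dimension mismatch between A and Q")
  e <- eigen(A)
  if (max(Re(e$values)) >= 0)
    stop("system unstable; reduce G or delta")
  V <- e$vectors
  W <- solve(V)
  Qt <- W %*% Q %*% Conj(t(W))
  denom <- outer(e$values, Conj(e$values), "+")
  Pt <- -Qt / denom
  P <- V %*% Pt %*% Conj(t(V))
  P <- Re(P)
  P <- (P + t(P)) / 2
  res <- max(abs(A %*% P + P %*% t(A) + Q))
  if (res > 1e-8 * max(max(abs(Q)), .Machine$double.eps))
    stop(sprintf("Lyapunov residual %.3e exceeds tolerance", res))
  P
}

#' @rdname solve_lyapunov
#' @export
solve_state_covariance <- solve_lyapunov

#' BOLD readout matrix
#'
#' The N x 6N matrix of partial derivatives of the BOLD equation with
#' respect to the full state, evaluated at the hemodynamic operating point.
#' Nonzero entries occur only in each node's blood-volume and
#' deoxyhemoglobin columns.
#'
#' @param hemo_ss hemodynamic steady state (list with `v`, `q`).
#' @param hp a [hemo_params()] object.
#' @return N x 6N matrix `K`.
#' @export
bold_readout <- function(hemo_ss, hp) {
  n <- length(hemo_ss$v)
  K <- matrix(0, n, 6L * n)
  p <- bold_partials(hemo_ss$v, hemo_ss$q, hp)
  for (i in seq_len(n)) {
    off <- 6L * (i - 1L)
    K[i, off + 5L] <- p$dv[i]
    K[i, off + 6L] <- p$dq[i]
  }
  K
}

#' BOLD covariance from the state covariance
#'
#' `P_BOLD = K P K^T` (all quantities real, so the conjugate transpose is the
#' ordinary transpose).
#'
#' @param P 6N x 6N state covariance.
#' @param K N x 6N BOLD readout matrix.
#' @return N x N symmetric BOLD covariance.
#' @export
bold_covariance <- function(P, K) {
  if (ncol(K) != nrow(P)) stop("dimension mismatch between K and P")
  PB <- K %*% P %*% t(K)
  (PB + t(PB)) / 2
}

#' Analytic global signal regression on a covariance matrix
#'
#' Removes the global-signal component directly in covariance space:
#' `Cov(e_i, e_j) = Cov(y_i, y_j) - sum_k Cov(y_i, y_k) * sum_l Cov(y_j, y_l)
#' / sum_{m,n} Cov(y_m, y_n)`. This is exactly the covariance of the
#' residuals of regressing each signal on the summed (global) signal, so
#' every row of the output sums to zero and the operation is idempotent.
#'
#' @param cov_mat symmetric covariance matrix.
#' @return GS-regressed covariance matrix (rows and columns sum to zero).
#' @export
gsr_covariance <- function(cov_mat) {
  cov_mat <- as.matrix(cov_mat)
  if (max(abs(cov_mat - t(cov_mat))) > 1e-8 * max(abs(cov_mat)))
    stop("covariance matrix must be symmetric")
  rs <- rowSums(cov_mat)
  tot <- sum(cov_mat)
  if (tot == 0) stop("total covariance is zero; global signal is degenerate")
  out <- cov_mat - outer(rs, rs) / tot
  (out + t(out)) / 2
}

#' Full semi-analytic covariance pipeline for one operating point
#'
#' Convenience wrapper: solves the fixed point, linearizes the combined
#' neural-hemodynamic system, solves the Lyapunov equation, and projects to
#' BOLD covariance (optionally GS-regressed).
#'
#' @inheritParams build_jacobian
#' @param gsr apply analytic global signal regression to the BOLD covariance.
#' @param ss optional precomputed steady state.
#' @return An object of class `cov_result`: list with `ss`, `A`, `Q`, `P`,
#'   `K`, `P_BOLD` (and `P_BOLD_raw` when `gsr = TRUE`).
#' @export
model_covariance <- function(sc, params, gains = NULL, w_EI = NULL,
                             hp = hemo_params(), gsr = FALSE, ss = NULL) {
  n <- sc$n
  if (is.null(gains)) gains <- modulate_gain(params, NULL, n)
  if (is.null(ss)) ss <- solve_fixed_point(sc, params, gains, w_EI)
  if (!isTRUE(ss$stable)) stop("system unstable; reduce G or delta")
  hss <- hemo_steady_state(ss$S_E, hp)
  A <- build_jacobian(ss, hss, sc, params, gains, w_EI, hp)
  if (max(Re(eigen(A, only.values = TRUE)$values)) >= 0)
    stop("system unstable; reduce G or delta")
  Q <- noise_covariance(n, params$sigma)
  P <- solve_lyapunov(A, Q)
  K <- bold_readout(hss, hp)
  PB <- bold_covariance(P, K)
  out <- list(ss = ss, hemo_ss = hss, A = A, Q = Q, P = P, K = K)
  if (gsr) {
    out$P_BOLD_raw <- PB
    out$P_BOLD <- gsr_covariance(PB)
  } else {
    out$P_BOLD <- PB
  }
  dimnames(out$P_BOLD) <- list(sc$labels, sc$labels)
  structure(out, class = "cov_result")
}

#' @export
print.cov_result <- function(x, ...) {
  n <- nrow(x$P_BOLD)
  cat(sprintf("Linearized covariance: %d nodes (state dimension %d)\n",
              n, nrow(x$A)))
  cat(sprintf("  max Re(eig A) = %.4f\n",
              max(Re(eigen(x$A, only.values = TRUE)$values))))
  invisible(x)
}
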