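# Combined drift of the 6N system in the blocked per-node ordering, used as
# the finite-difference oracle for the analytic Jacobian.
combined_drift <- function(z, sc, p, gains, w_EI, hp) {
  n <- sc$n
  Z <- matrix(z, 6, n)
  f <- drift(Z[1, ], Z[2, ], sc, p, gains, w_EI)
  h <- hemo_drift(list(x = Z[3, ], f = Z[4, ], v = Z[5, ], q = Z[6, ]),
                  Z[1, ], hp)
  as.vector(rbind(f$dS_E, f$dS_I, h$dx, h$df, h$dv, h$dq))
}

test_that("analytic Jacobian matches central finite differences and has the
           expected structure", {
  sc <- sc5()
  p <- dmf_params(G = 0.5)
  hp <- hemo_params()
  w_EI <- apply_fic(sc, p)
  gains <- modulate_gain(p, NULL, 5)
  ss <- solve_fixed_point(sc, p, w_EI = w_EI)
  hss <- hemo_steady_state(ss$S_E, hp)
  A <- build_jacobian(ss, hss, sc, p, gains, w_EI, hp)
  expect_lt(max(Re(eigen(A, only.values = TRUE)$values)), 0)

  z0 <- as.vector(rbind(ss$S_E, ss$S_I, hss$x, hss$f, hss$v, hss$q))
  eps <- 1e-6
  A_fd <- matrix(0, 30, 30)
  for (j in 1:30) {
    zp <- z0; zm <- z0
    zp[j] <- zp[j] + eps; zm[j] <- zm[j] - eps
    A_fd[, j] <- (combined_drift(zp, sc, p, gains, w_EI, hp) -
                    combined_drift(zm, sc, p, gains, w_EI, hp)) / (2 * eps)
  }
  expect_lt(max(abs(A - A_fd)) / max(abs(A)), 1e-6)

  # hemodynamics are blind to the inhibitory gating
  iSI <- 6 * (0:4) + 2
  ihemo <- as.vector(outer(3:6, 6 * (0:4), "+"))
  expect_true(all(A[ihemo, iSI] == 0))
})

test_that("Lyapunov solver reproduces closed forms and simulated linear
           dynamics", {
  # scalar Ornstein-Uhlenbeck: P = sigma^2 / (2 theta)
  expect_equal(solve_lyapunov(matrix(-2), matrix(0.3^2))[1, 1],
               0.3^2 / (2 * 2), tolerance = 1e-12)
  # diagonal system with independent noise stays diagonal
  A <- diag(c(-1, -3, -0.5))
  Q <- diag(c(1, 2, 0.4))
  P <- solve_lyapunov(A, Q)
  expect_equal(P, diag(diag(P)), tolerance = 1e-12)
  expect_equal(diag(P), diag(Q) / (2 * abs(diag(A))))

  # random stable systems: residual bound and PSD
  set.seed(10)
  for (rep in 1:5) {
    M <- matrix(rnorm(144), 12)
    A <- M - diag(12) * (max(Re(eigen(M, only.values = TRUE)$values)) + 0.5)
    B <- matrix(rnorm(144), 12)
    Q <- crossprod(B) / 12
    P <- solve_lyapunov(A, Q)
    expect_lt(max(abs(A %*% P + P %*% t(A) + Q)), 1e-8 * max(abs(Q)))
    expect_true(all(eigen(P, symmetric = TRUE, only.values = TRUE)$values >
                      -1e-10))
  }
  expect_error(solve_lyapunov(matrix(1), matrix(1)), "unstable")
})

test_that("Lyapunov covariance matches the time-average covariance of a
           simulated linear SDE", {
  set.seed(21)
  M <- matrix(rnorm(16), 4)
  A <- M - diag(4) * (max(Re(eigen(M, only.values = TRUE)$values)) + 1)
  Q <- diag(0.1, 4)
  P <- solve_lyapunov(A, Q)
  # Euler-Maruyama oracle
  z <- rep(0, 4)
  dt <- 2e-3
  n_steps <- 4e5
  acc <- matrix(0, 4, 4)
  L <- sqrt(diag(Q) * dt)
  for (i in seq_len(n_steps)) {
    z <- z + A %*% z * dt + L * rnorm(4)
    if (i > 1000) acc <- acc + tcrossprod(z)
  }
  P_sim <- acc / (n_steps - 1000)
  expect_lt(max(abs(P_sim - P)) / max(abs(P)), 0.1)
})

test_that("analytic GSR matches hand evaluation, zeroes row sums, and is
           idempotent", {
  # 2x2 identity covariance: the global signal is y1 + y2, each slope is
  # 1/2, residuals are (y1 - y2)/2 and (y2 - y1)/2, hence variance 1/2
  expect_equal(gsr_covariance(diag(2)),
               matrix(c(0.5, -0.5, -0.5, 0.5), 2))
  set.seed(30)
  B <- matrix(rnorm(64), 8)
  C <- crossprod(B)
  G1 <- gsr_covariance(C)
  expect_lt(max(abs(rowSums(G1))), 1e-12 * max(abs(C)))
  expect_equal(G1, t(G1))
  # covariance scale of the dmfgain BOLD outputs is ~1e-9; use relative check
  expect_equal(gsr_covariance(G1 + diag(1e-10, 8)),
               gsr_covariance(C + 0), tolerance = 1e-6)
})

test_that("analytic GSR equals the covariance of time-domain global-signal
           regression residuals", {
  set.seed(31)
  n <- 6; T_len <- 400
  L <- matrix(rnorm(n * n), n)
  Y <- matrix(rnorm(T_len * n), T_len) %*% L   # correlated series
  S <- stats::cov(Y)
  gs <- rowSums(Y)
  resid <- apply(Y, 2, function(y) stats::residuals(stats::lm(y ~ gs)))
  expect_equal(gsr_covariance(S), stats::cov(resid), tolerance = 1e-10)
})

test_that("BOLD covariance projection is correct and correlations are
           invariant to the noise amplitude", {
  sc <- sc5()
  p <- dmf_params(G = 0.5, sigma = 0.01)
  m <- dmf_model(sc, p)
  cv <- model_covariance(sc, p, w_EI = m$w_EI, ss = m$baseline)
  expect_equal(cv$P_BOLD, t(cv$P_BOLD))
  expect_true(all(eigen(cv$P_BOLD, symmetric = TRUE,
                        only.values = TRUE)$values > -1e-15))
  expect_equal(unname(cv$P_BOLD), bold_covariance(cv$P, cv$K))
  expect_equal(bold_covariance(cv$P, 0 * cv$K), matrix(0, 5, 5))
  # single node scalar expansion
  k_v <- cv$K[1, 5]; k_q <- cv$K[1, 6]
  expect_equal(cv$P_BOLD[1, 1],
               k_v^2 * cv$P[5, 5] + 2 * k_v * k_q * cv$P[5, 6] +
                 k_q^2 * cv$P[6, 6])
  # sigma invariance of correlations
  p2 <- dmf_params(G = 0.5, sigma = 0.037)
  cv2 <- model_covariance(sc, p2, w_EI = m$w_EI, ss = m$baseline)
  expect_equal(cov_to_fc(cv$P_BOLD), cov_to_fc(cv2$P_BOLD),
               tolerance = 1e-12)
})

test_that("analytic BOLD correlations approximate the nonlinear simulation
           and the gap shrinks with the noise amplitude", {
  sc <- sc10()
  simfc <- function(sig, T_total) {
    p <- dmf_params(G = 0.5, sigma = sig)
    m <- dmf_model(sc, p)
    sim <- simulate(m, nsim = T_total, seed = 7, tr = 1, burn_in = 20)
    cor(sim$bold)
  }
  p <- dmf_params(G = 0.5, sigma = 0.01)
  m <- dmf_model(sc, p)
  cv <- model_covariance(sc, p, w_EI = m$w_EI, ss = m$baseline)
  fc_a <- cov_to_fc(cv$P_BOLD)
  expect_lt(max(abs(unname(fc_a) - simfc(0.01, 4000))), 0.1)
  # paired common-noise design isolates the linearization error from the
  # (sigma-invariant) sampling error
  ref <- simfc(1e-4, 2000)
  gaps <- vapply(c(0.02, 0.01, 0.005),
                 function(s) max(abs(simfc(s, 2000) - ref)), numeric(1))
  expect_true(all(diff(gaps) < 0))
})
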