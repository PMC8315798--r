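test_that("transfer function is continuous, positive, increasing, and matches
           reference evaluations", {
  # removable singularity: phi(b/a) = 1/d
  expect_equal(transfer_rate(125 / 310, 310, 125, 0.16), 1 / 0.16)
  for (eps in c(-1e-9, 1e-9)) {
    expect_lt(abs(transfer_rate(125 / 310 + eps, 310, 125, 0.16) - 6.25), 1e-6)
  }
  # high-precision scalar evaluation at the background current
  # (independently verified value of (a*I-b)/(1-exp(-d*(a*I-b))) at I=0.382)
  expect_equal(transfer_rate(0.382, 310, 125, 0.16), 3.5268949118680327,
               tolerance = 1e-12)
  # asymptotically linear for strong input
  I_big <- 100
  expect_equal(transfer_rate(I_big, 310, 125, 0.16) / (310 * I_big - 125), 1,
               tolerance = 1e-12)
  # strictly increasing and strictly positive over a wide range
  I <- seq(-5, 5, length.out = 2001)
  r <- transfer_rate(I, 310, 125, 0.16)
  expect_true(all(r > 0))
  expect_true(all(diff(r) > 0))
  expect_error(transfer_rate(NaN, 310, 125, 0.16), "non-finite")
})

test_that("transfer slope matches numerical differentiation", {
  I <- c(-0.5, 0.1, 125 / 310, 0.4031, 0.5, 2)
  eps <- 1e-7
  num <- (transfer_rate(I + eps, 310, 125, 0.16) -
            transfer_rate(I - eps, 310, 125, 0.16)) / (2 * eps)
  expect_equal(transfer_slope(I, 310, 125, 0.16), num, tolerance = 1e-5)
})

test_that("gain modulation scales the gain constants and is neutral at
           delta = 0", {
  p <- dmf_params()
  h <- c(0, 0.5, 1)
  expect_equal(modulate_gain(p, gain_mod(h, 0, 0), 3)$a_E, rep(310, 3))
  expect_identical(modulate_gain(p, gain_mod(h, 0, 0), 3),
                   modulate_gain(p, NULL, 3))
  m <- modulate_gain(p, gain_mod(h, 0.03, 0.01), 3)
  expect_equal(m$a_E[3], 1.03 * 310)
  expect_equal(m$a_E[1], 310)
  expect_equal(m$a_I[2], (1 + 0.5 * 0.01) * 615)
  expect_error(modulate_gain(p, gain_mod(rep(1, 3), -1.5, 0), 3),
               "non-positive")
})

test_that("vectorized drift matches a hand-coded scalar loop", {
  sc <- sc5()
  p <- dmf_params(G = 0.4)
  set.seed(42)
  S_E <- runif(5)
  S_I <- runif(5, 0, 0.3)
  h <- runif(5)
  gains <- modulate_gain(p, gain_mod(h, 0.02, 0.01), 5)
  w_EI <- runif(5, 0.8, 1.5)
  got <- drift(S_E, S_I, sc, p, gains, w_EI)
  ref <- drift_loop(S_E, S_I, sc$C, p, gains$a_E, gains$a_I, w_EI)
  expect_equal(got$dS_E, ref$dS_E, tolerance = 1e-12)
  expect_equal(got$dS_I, ref$dS_I, tolerance = 1e-12)
  # saturation: at S_E = 1 the excitatory gating can only decrease
  full <- drift(rep(1, 5), S_I, sc, p, gains, w_EI)
  expect_true(all(full$dS_E < 0))
  expect_error(drift(S_E[1:3], S_I, sc, p), "dimension")
})

test_that("fixed-point solver converges to a drift-free, stable state and is
           invariant to an explicit zero modulation", {
  sc <- sc10()
  p <- dmf_params(G = 0.5)
  ss <- solve_fixed_point(sc, p)
  expect_lt(ss$residual, 1e-10)
  f <- drift(ss$S_E, ss$S_I, sc, p)
  expect_lt(max(abs(c(f$dS_E, f$dS_I))), 1e-10)
  expect_true(ss$stable)
  expect_equal(ss$r_E, transfer_rate(ss$I_E, p$a_E, p$b_E, p$d_E))
  # delta = 0 passed explicitly gives a bit-identical state
  g0 <- modulate_gain(p, gain_mod(rep(0.5, 10), 0, 0), 10)
  ss0 <- solve_fixed_point(sc, p, gains = g0)
  expect_identical(ss$S_E, ss0$S_E)
  expect_identical(ss$S_I, ss0$S_I)
})

test_that("fixed point agrees with long noise-free forward integration", {
  sc <- sc10()
  p <- dmf_params(G = 0.5)
  w_EI <- apply_fic(sc, p)
  ss <- solve_fixed_point(sc, p, w_EI = w_EI)
  # independent Euler oracle from a displaced initial condition
  S_E <- rep(0.05, 10); S_I <- rep(0.05, 10)
  dt <- 1e-4
  for (i in seq_len(200000)) {      # 20 s of model time
    f <- drift(S_E, S_I, sc, p, w_EI = w_EI)
    S_E <- S_E + dt * f$dS_E
    S_I <- S_I + dt * f$dS_I
  }
  expect_equal(S_E, ss$S_E, tolerance = 1e-6)
  expect_equal(S_I, ss$S_I, tolerance = 1e-6)
})

test_that("feedback inhibition control pins excitatory rates at the target", {
  sc <- sc30()
  p <- dmf_params(G = 0.5)
  w_EI <- apply_fic(sc, p)
  expect_true(all(w_EI > 0))
  ss <- solve_fixed_point(sc, p, w_EI = w_EI)
  expect_true(all(abs(ss$r_E - 3) < 1e-6))
  # isolated nodes (G = 0)
  p0 <- dmf_params(G = 0)
  ss0 <- solve_fixed_point(sc, p0, w_EI = apply_fic(sc, p0))
  expect_true(all(abs(ss0$r_E - 3) < 1e-6))
  # symmetry: two identical, symmetrically coupled nodes get equal weights
  sym <- dmf_connectome(matrix(c(0, 1, 1, 0), 2), labels = c("a", "b"))
  expect_equal(diff(apply_fic(sym, dmf_params(G = 0.3))), 0)
})

test_that("analytic FIC matches an iterative tuning loop", {
  sc <- fixture("sc20", function() make_connectome(20, seed = 7))
  p <- dmf_params(G = 0.5)
  w_analytic <- apply_fic(sc, p)
  # independent oracle: adjust each node's w_EI by bisection-style feedback,
  # re-solving the full fixed point each round
  w <- rep(1, 20)
  for (it in 1:200) {
    ss <- solve_fixed_point(sc, p, w_EI = w)
    err <- ss$r_E - 3
    if (max(abs(err)) < 1e-9) break
    w <- w * (1 + 0.05 * err)    # more inhibition when rates run high
  }
  expect_lt(max(abs(ss$r_E - 3)), 1e-9)
  expect_equal(w, w_analytic, tolerance = 1e-6)
})

test_that("forward integration keeps gating within physical bounds", {
  sc <- sc5()
  p <- dmf_params(G = 0.5, sigma = 0.05)  # strong noise to stress the clamps
  m <- dmf_model(sc, p)
  set.seed(5)
  sim <- simulate_sde(sc, p, w_EI = m$w_EI, T_total = 30, burn_in = 0,
                      tr = 0.1, seed = 9, keep_synaptic = TRUE,
                      init = list(S_E = runif(5), S_I = runif(5)))
  expect_true(all(sim$S_E >= 0 & sim$S_E <= 1))
  expect_true(all(sim$S_I >= 0))
})
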