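test_that("map PCA matches an independent SVD route and conserves
           variance", {
  set.seed(20)
  X <- matrix(rnorm(24), 4, 6)
  p <- map_pca(X)
  Xc <- scale(X, scale = FALSE)
  s <- svd(Xc)
  expect_equal(p$lambda[1:3], s$d[1:3]^2 / 3, tolerance = 1e-10)
  for (j in 1:3) {
    v <- s$v[, j]
    if (v[which.max(abs(v))] < 0) v <- -v
    expect_equal(unname(p$P[, j]), v, tolerance = 1e-8)
  }
  expect_equal(sum(p$lambda), sum(diag(crossprod(Xc) / 3)))
  expect_lt(max(abs(crossprod(p$P) - diag(6))), 1e-10)
  # sign convention: largest-magnitude element positive
  expect_true(all(apply(p$P, 2, function(v) v[which.max(abs(v))] >= 0)))
  # reconstruction from scores
  expect_lt(max(abs(Xc - p$scores %*% t(p$P))), 1e-8)
  # two distinct maps span exactly one dimension after centering
  p2 <- map_pca(X[1:2, ])
  expect_equal(sum(p2$lambda > 1e-12 * p2$lambda[1]), 1L)
  expect_error(map_pca(X[1, , drop = FALSE]), "two maps")
})

test_that("PC permutation test flags a planted spatial mode and nothing
           else", {
  set.seed(21)
  n <- 40; M <- 16
  mode <- sin(seq_len(n) / 3)
  loadings <- rnorm(M, 0, 5)
  X <- outer(loadings, mode) + matrix(rnorm(M * n), M, n)  # SNR ~5:1
  pt <- pc_permutation_test(X, n_perm = 200, seed = 2)
  expect_true(pt$significant[1])
  expect_false(any(pt$significant[3:10]))
  # every permutation's variance fractions sum to one
  expect_equal(rowSums(pt$null), rep(1, 200))
  # negative control: destroying the rows' shared structure first
  Xn <- t(apply(X, 1, sample))
  ptn <- pc_permutation_test(Xn, n_perm = 200, seed = 3)
  expect_lt(sum(ptn$significant), 3)
  expect_warning(pc_permutation_test(X, n_perm = 50, seed = 1), "100")
})

test_that("subspace variance fraction reduces to cumulative variance on the
           covariance's own principal axes", {
  set.seed(22)
  B <- matrix(rnorm(100), 10)
  C <- crossprod(B) / 10
  e <- eigen(C, symmetric = TRUE)
  expect_equal(subspace_variance_fraction(C, e$vectors), 1)
  for (k in c(1, 3, 5)) {
    expect_equal(subspace_variance_fraction(C, e$vectors[, 1:k]),
                 sum(e$values[1:k]) / sum(e$values))
  }
  # projection oracle: project data, recompute covariance, compare traces
  X <- matrix(rnorm(200 * 10), 200) %*% chol(C)
  P <- qr.Q(qr(matrix(rnorm(40), 10, 4)))
  Cs <- stats::cov(X)
  expect_equal(subspace_variance_fraction(Cs, P),
               sum(diag(stats::cov(X %*% P))) / sum(diag(Cs)))
  expect_true(subspace_variance_fraction(C, P) >= 0 &&
                subspace_variance_fraction(C, P) <= 1)
  expect_error(subspace_variance_fraction(C, 2 * e$vectors), "orthonormal")
})

test_that("experiential regression maps recover planted linear relations and
           the closed-form OLS oracle", {
  set.seed(23)
  M <- 12; n <- 9
  dg <- matrix(rnorm(M * n), M, n)
  # exact linear relation at parcel 7
  scores <- cbind(a = 2 * dg[, 7] + 1, b = rnorm(M))
  rm <- experiential_regression_maps(dg, scores)
  expect_equal(rm$beta[7, "a"], 2)
  expect_equal(rm$alpha[7, "a"], 1)
  # constant scores give zero slopes
  rm0 <- experiential_regression_maps(dg, cbind(k = rep(4, M)))
  expect_true(all(rm0$beta == 0))
  expect_true(all(rm0$alpha == 4))
  # closed-form cov/var oracle and lm cross-check
  for (i in c(1, 5, 9)) for (d in 1:2) {
    expect_equal(rm$beta[i, d], cov(dg[, i], scores[, d]) / var(dg[, i]))
    fit <- lm(scores[, d] ~ dg[, i])
    expect_equal(unname(rm$beta[i, d]), unname(coef(fit)[2]))
    expect_equal(unname(rm$alpha[i, d]), unname(coef(fit)[1]))
  }
  dg2 <- dg; dg2[, 3] <- 1
  expect_warning(experiential_regression_maps(dg2, scores), "constant")
})

test_that("a cohort with one latent experiential driver yields a dominant
           regression-map PC1", {
  sc <- sc30()
  h <- h30()
  g <- unname(h$values - mean(h$values))
  set.seed(24)
  # five score dimensions all coupled to the same latent spatial pattern
  cohort <- make_cohort(brain_map(g, sc$labels), n_subjects = 24,
                        noise_sd = 0.05, seed = 25)
  A1 <- outer(g / sqrt(sum(g^2)), runif(5, 0.5, 1.5))
  scores <- cohort$dgbc %*% A1 + matrix(rnorm(24 * 5, 0, 0.05), 24, 5)
  rm <- experiential_regression_maps(cohort$dgbc, scores)
  p <- map_pca(t(rm$beta))
  expect_gt(p$var_frac[1], 0.5)
})
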