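test_that("variogram matches exhaustive pair enumeration and handles
           degenerate maps", {
  set.seed(12)
  xy <- matrix(runif(12), 6, 2)
  D <- as.matrix(dist(xy))
  x <- rnorm(6)
  vg <- variogram(x, D, n_bins = 3)
  # brute-force oracle over all 15 pairs
  breaks <- seq(0, max(D[upper.tri(D)]), length.out = 4)
  for (b in seq_len(nrow(vg))) {
    vals <- c()
    for (i in 1:5) for (j in (i + 1):6) {
      bin <- cut(D[i, j], breaks, include.lowest = TRUE, labels = FALSE)
      if (!is.na(bin) && breaks[bin] <= vg$center[b] &&
          vg$center[b] <= breaks[bin + 1])
        vals <- c(vals, 0.5 * (x[i] - x[j])^2)
    }
    expect_equal(vg$semivariance[b], mean(vals))
  }
  # constant map: zero semivariance everywhere
  vg0 <- suppressWarnings(variogram(rep(2, 6), D, n_bins = 3))
  expect_true(all(vg0$semivariance == 0))
})

test_that("an i.i.d. map has a flat variogram at the field variance", {
  sc <- fixture("sc80", function() make_connectome(80, seed = 13))
  reps <- 40
  set.seed(14)
  acc <- NULL
  for (r in seq_len(reps)) {
    vg <- variogram(rnorm(80), sc$D, n_bins = 8)
    acc <- if (is.null(acc)) vg$semivariance else acc + vg$semivariance
  }
  mean_sv <- acc / reps
  # each bin estimates the variance (= 1); allow 3 standard errors
  se <- 1 / sqrt(reps * 8)
  expect_true(all(abs(mean_sv - 1) < 3 * se * sqrt(8)))
})

test_that("surrogates preserve the value multiset and the empirical
           variogram, unlike naive permutations", {
  sc <- fixture("sc60", function() make_connectome(60, seed = 4))
  h <- make_expression_map(sc, autocorr_length = 60, seed = 5)
  vg <- variogram(h, sc$D)
  rel_sse <- function(a) sum((a - vg$semivariance)^2) / sum(vg$semivariance^2)
  n_draws <- 15
  surr_sv <- perm_sv <- 0
  set.seed(123)
  for (s in seq_len(n_draws)) {
    surr <- generate_surrogate(h, sc$D, seed = s)
    expect_identical(sort(unname(surr$values)), sort(unname(h$values)))
    surr_sv <- surr_sv + variogram(surr, sc$D)$semivariance
    perm_sv <- perm_sv + variogram(sample(unname(h$values)), sc$D)$semivariance
  }
  expect_lt(rel_sse(surr_sv / n_draws), 0.2)
  expect_gt(rel_sse(perm_sv / n_draws), 0.2)
  # constant map round-trips unchanged
  const <- brain_map(rep(0.4, 60), sc$labels)
  expect_equal(generate_surrogate(const, sc$D, seed = 1)$values, const$values)
})

test_that("surrogate ensembles are seed-reproducible", {
  sc <- fixture("sc60", function() make_connectome(60, seed = 4))
  h <- make_expression_map(sc, autocorr_length = 60, seed = 5)
  s1 <- generate_surrogate(h, sc$D, seed = 42)
  s2 <- generate_surrogate(h, sc$D, seed = 42)
  s3 <- generate_surrogate(h, sc$D, seed = 43)
  expect_identical(s1$values, s2$values)
  expect_false(identical(s1$values, s3$values))
})

test_that("null-test p-values follow the proportion convention", {
  sc <- sc30()
  h <- h30()
  # constant statistic: every null sample ties the observed value
  t1 <- surrogate_null_test(function(m) 1, h, sc$D, n_surrogates = 20,
                            seed = 1)
  expect_equal(t1$p_value, 1)
  # statistic that deterministically ranks the empirical map above all
  # surrogates (its own topography)
  target <- unname(h$values - mean(h$values))
  t2 <- surrogate_null_test(function(m) -sum((unname(m$values) -
                                                mean(m$values) - target)^2),
                            h, sc$D, n_surrogates = 20, seed = 1)
  expect_equal(t2$p_value, 0)
  t2c <- surrogate_null_test(function(m) -sum((unname(m$values) -
                                                 mean(m$values) - target)^2),
                             h, sc$D, n_surrogates = 20, seed = 1,
                             conservative = TRUE)
  expect_equal(t2c$p_value, 1 / 21)
})

test_that("surrogate null p-values are approximately uniform for maps
           without spatial structure", {
  sc <- fixture("sc25", function() make_connectome(25, seed = 17))
  probe <- sin(seq_len(25))         # fixed arbitrary comparison pattern
  stat <- function(m) cor(unname(m$values), probe)
  n_draws <- 120
  pvals <- numeric(n_draws)
  for (r in seq_len(n_draws)) {
    set.seed(1000 + r)
    flat_map <- brain_map(runif(25), sc$labels)   # no autocorrelation
    tt <- surrogate_null_test(stat, flat_map, sc$D, n_surrogates = 49,
                              seed = r * 50, conservative = TRUE)
    pvals[r] <- tt$p_value
  }
  ks <- suppressWarnings(ks.test(pvals, "punif"))
  expect_gt(ks$p.value, 0.01)
})
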