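test_that("one-dimensional and identity-whitened cases are exact", {
  b <- block_correlation(matrix(1), matrix(0.6), matrix(1))
  expect_equal(canonical_correlations(b), 0.6, tolerance = 1e-12)

  b2 <- block_correlation(diag(2), diag(c(0.9, 0.3)), diag(2))
  expect_equal(canonical_correlations(b2), c(0.9, 0.3), tolerance = 1e-12)
})

test_that("eigenproblem solutions match the SVD-whitening oracle", {
  for (i in 1:200) {
    m <- sample(1:5, 1); n <- sample(1:5, 1)
    b <- make_random_block(m, n, seed = i)
    expect_equal(canonical_correlations(b), oracle_cca(b),
                 tolerance = 1e-8)
  }
})

test_that("rank-deficient blocks are handled by the pseudo-inverse", {
  # exactly collinear sites (as in two-site relative usage)
  pp <- matrix(c(1, -1, -1, 1), 2)
  qq <- diag(2)
  pq <- rbind(c(0.8, 0), c(-0.8, 0))
  xi <- canonical_correlations(block_correlation(pp, pq, qq))
  expect_length(xi, 2)
  expect_true(all(is.finite(xi)))
  expect_true(all(xi >= 0 & xi < 1))
  expect_error(block_correlation(pp * NA, pq, qq), "non-finite")
})

test_that("the sequential likelihood-ratio example reproduces exactly", {
  s <- significance_sequence(c(0.9, 0.3), m = 2, n = 2, g = 10)
  expect_equal(s$statistic[1], -8 * (log(0.19) + log(0.91)),
               tolerance = 1e-12)
  expect_equal(s$statistic[2], -8 * log(0.91), tolerance = 1e-12)
  expect_equal(s$statistic, c(14.040, 0.754), tolerance = 1e-3)
  expect_equal(s$df, c(4, 1))
  # independent chi-square tail oracle by Monte Carlo-free closed form:
  # df=4 upper tail is exp(-x/2) * (1 + x/2); df=1 is 2 * (1 - pnorm(sqrt(x)))
  x1 <- s$statistic[1]
  expect_equal(s$p_value[1], exp(-x1 / 2) * (1 + x1 / 2), tolerance = 1e-12)
  expect_equal(s$p_value[2], 2 * (1 - pnorm(sqrt(s$statistic[2]))),
               tolerance = 1e-12)
  expect_equal(s$n_significant, 1L)
  expect_equal(s$significant, c(TRUE, FALSE))
})

test_that("null and near-unity canonical correlations behave at the limits", {
  s0 <- significance_sequence(rep(0, 3), 3, 3, g = 10)
  expect_equal(s0$statistic, rep(0, 3))
  expect_equal(s0$p_value, rep(1, 3))
  expect_equal(s0$n_significant, 0L)

  s1 <- significance_sequence(c(sqrt(1 - 1e-12), 0.1), 2, 2, g = 10)
  expect_lt(s1$p_value[1], 1e-10)
  expect_true(s1$significant[1])

  expect_error(significance_sequence(0.5, 3, 4, g = 3), "sample size")
  expect_error(significance_sequence(1, 1, 1, g = 10))
})

test_that("weights combine significant coefficients by -log p", {
  # only the first coefficient significant: weight equals xi1 exactly
  t1 <- list(significant = c(TRUE, FALSE), p_value = c(0.01, 0.4))
  expect_identical(pair_weight(c(0.73, 0.5), t1), 0.73)

  t2 <- list(significant = c(TRUE, TRUE), p_value = c(0.001, 0.01))
  w <- (0.8 * -log(0.001) + 0.5 * -log(0.01)) /
       (-log(0.001) - log(0.01))
  expect_equal(pair_weight(c(0.8, 0.5), t2), w)
  expect_equal(pair_weight(c(0.8, 0.5), t2), 0.6800, tolerance = 1e-4)

  t3 <- list(significant = c(FALSE, FALSE), p_value = c(0.2, 0.9))
  expect_identical(pair_weight(c(0.8, 0.5), t3), 0)
})

test_that("weights are symmetric, bounded by xi1, and site-order invariant", {
  for (i in 1:25) {
    m <- sample(1:4, 1); n <- sample(1:4, 1)
    b <- make_random_block(m, n, obs = 12, seed = 100 + i)
    xi <- canonical_correlations(b)
    s <- significance_sequence(xi, m, n, g = 12)
    w <- pair_weight(xi, s)
    expect_gte(w, 0); expect_lte(w, 1)
    expect_lte(w, xi[1] + 1e-12)
    # swapping the two gene blocks leaves xi and w unchanged
    bs <- block_correlation(b$qq, t(b$pq), b$pp)
    expect_equal(canonical_correlations(bs), xi, tolerance = 1e-8)
    # permuting sites within a block leaves the spectrum unchanged
    pm <- sample(m)
    bp <- block_correlation(b$pp[pm, pm, drop = FALSE],
                            b$pq[pm, , drop = FALSE], b$qq)
    expect_equal(canonical_correlations(bp), xi, tolerance = 1e-8)
  }
})

test_that("single-site gene pairs reduce to the absolute correlation", {
  lam <- -0.85
  b <- block_correlation(matrix(1), matrix(lam), matrix(1))
  xi <- canonical_correlations(b)
  expect_equal(xi, abs(lam), tolerance = 1e-12)
  s <- significance_sequence(xi, 1, 1, g = 20)
  w <- pair_weight(xi, s)
  expect_equal(w, if (s$n_significant >= 1) abs(lam) else 0)
  expect_equal(s$n_significant, 1L)  # |r| = 0.85 at g = 20 rejects
})
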