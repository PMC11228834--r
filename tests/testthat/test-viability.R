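test_that("viability_matrix validates symmetry, bounds and primary effects", {
  expect_error(viability_matrix(matrix(c(0.1, 0.2, 0.3, 0.4), 2)),
               "symmetric")
  expect_error(viability_matrix(matrix(1.2, 1, 1)), "\\[0, 1\\]")
  expect_error(viability_matrix(matrix(0.5, 2, 2), X = 0.5), "per allele")
  expect_error(viability_matrix(matrix(0.5, 1, 1), X = 0.5, alpha = 0.6),
               "alpha")
  expect_error(viability_matrix(matrix(0.5, 1, 1), alpha = 0.3),
               "primary effects")
  W <- viability_matrix(matrix(c(0.2, 0.7, 0.7, 0.9), 2),
                        X = c(0.1, 0.8), alpha = 1 / 3)
  expect_identical(W$method, "gendom")
  expect_identical(n_alleles(W), 2L)
})

test_that("uniform mutant viabilities extend the matrix with fresh U[0,1] draws", {
  W <- fixture_matrix("initial")
  set.seed(31)
  W2 <- add_mutant(W)
  set.seed(31)
  u <- runif(2)
  expect_equal(W2$w, matrix(c(0.5, u[1], u[1], u[2]), 2))

  set.seed(8)
  W3 <- viability_matrix(random_sym_matrix(4))
  W4 <- add_mutant(W3)
  expect_identical(n_alleles(W4), 5L)
  expect_equal(W4$w[1:4, 1:4], W3$w)       # existing entries untouched
  expect_identical(W4$w, t(W4$w))
  expect_true(all(W4$w >= 0 & W4$w <= 1))
})

test_that("generalized dominance combines primary and interaction effects", {
  W <- viability_matrix(matrix(c(0.2, 0.7, 0.7, 0.9), 2),
                        X = c(0.6, 0.3), alpha = 1 / 3)
  set.seed(17)
  W2 <- add_mutant(W)
  set.seed(17)
  Xn <- runif(1)
  Y <- runif(3)
  a <- 1 / 3
  expect_equal(W2$w[, 3], a * (c(0.6, 0.3, Xn) + Xn) + (1 - 2 * a) * Y)
  expect_equal(W2$X, c(0.6, 0.3, Xn))
  expect_equal(W2$w[1:2, 1:2], W$w)
  expect_identical(W2$w, t(W2$w))

  # single-allele start: w11 = 2*alpha*X1 + (1 - 2*alpha)*Y11
  set.seed(23)
  W0 <- init_viability("gendom", alpha = 1 / 3)
  set.seed(23)
  d <- runif(2)
  expect_equal(W0$w[1, 1], 2 / 3 * d[1] + 1 / 3 * d[2])
  expect_equal(W0$X, d[1])
})

test_that("dominance-sharing correlation matches the closed form", {
  expect_equal(gendom_correlation(1 / 3), 1 / 3, tolerance = 1e-12)
  expect_identical(gendom_correlation(0), 0)
  expect_equal(gendom_correlation(0.5), 0.5, tolerance = 1e-12)
  expect_error(gendom_correlation(0.6), "alpha")
  expect_error(gendom_correlation(-0.1), "alpha")

  # Monte Carlo on shared-allele genotype pairs w_ij, w_ik
  set.seed(41)
  a <- 1 / 3
  m <- 2e4
  Xi <- runif(m); Xj <- runif(m); Xk <- runif(m)
  wij <- a * (Xi + Xj) + (1 - 2 * a) * runif(m)
  wik <- a * (Xi + Xk) + (1 - 2 * a) * runif(m)
  rho <- gendom_correlation(a)
  se <- (1 - rho^2) / sqrt(m)
  expect_lt(abs(cor(wij, wik) - rho), 4 * se)
})

test_that("constant decay scales viabilities and primary effects; d = 1 is the identity", {
  W <- viability_matrix(matrix(c(0.8, 0.4, 0.4, 0.6), 2),
                        X = c(0.5, 0.9), alpha = 0.2)
  expect_identical(apply_decay(W, decay_model("none")), W)
  expect_identical(apply_decay(W, decay_model("constant", d = 1))$w, W$w)
  dec <- apply_decay(W, decay_model("constant", d = 0.995))
  expect_equal(dec$w[1, 1], 0.796)
  expect_equal(dec$X, 0.995 * c(0.5, 0.9))
  # closed form after repeated application
  Wt <- W
  for (i in 1:50) Wt <- apply_decay(Wt, decay_model("constant", d = 0.999))
  expect_equal(Wt$w, 0.999^50 * W$w, tolerance = 1e-12)
  expect_error(decay_model("constant", d = 1.2), "d <= 1")
  expect_error(decay_model("constant", d = 0), "d <= 1")
})

test_that("stochastic decay draws per genotype pair, clamps to [0,1], keeps symmetry", {
  set.seed(6)
  W <- viability_matrix(random_sym_matrix(6))
  set.seed(99)
  dec <- apply_decay(W, decay_model("stochastic", mu = 0.999, sigma = 0.001))
  set.seed(99)
  dij <- rnorm(21, 0.999, 0.001)
  ut <- upper.tri(W$w, diag = TRUE)
  expect_equal(dec$w[ut], pmin(pmax(W$w[ut] * dij, 0), 1))
  expect_identical(dec$w, t(dec$w))

  # sigma -> 0 approaches the constant model
  set.seed(1)
  tiny <- apply_decay(W, decay_model("stochastic", mu = 0.9, sigma = 1e-12))
  expect_equal(tiny$w, 0.9 * W$w, tolerance = 1e-9)

  # clamping removes the upper tail: decaying w = 1 cannot gain fitness,
  # so the post-decay mean falls below mu
  ones <- viability_matrix(matrix(1, 150, 150))
  set.seed(2)
  d1 <- apply_decay(ones, decay_model("stochastic", mu = 0.999, sigma = 0.001))
  expect_true(all(d1$w <= 1))
  expect_lt(mean(d1$w[upper.tri(d1$w, diag = TRUE)]), 0.999)
  expect_error(decay_model("stochastic", sigma = 0), "sigma")
})

test_that("alpha = 0 generalized dominance is indistinguishable from uniform draws", {
  set.seed(12)
  W <- init_viability("gendom", alpha = 0)
  entries <- numeric(0)
  for (i in 1:140) {
    W <- add_mutant(W)
    entries <- c(entries, W$w[, n_alleles(W)])
  }
  expect_gt(stats::ks.test(entries, "punif")$p.value, 1e-3)
})
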