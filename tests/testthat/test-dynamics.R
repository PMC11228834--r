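W22 <- matrix(c(0.4, 1, 1, 0.6), 2)

test_that("marginal and mean fitness match direct evaluation", {
  expect_equal(marginal_fitness(c(0.8, 0.2), W22), c(0.52, 0.92))
  expect_equal(mean_fitness(c(0.8, 0.2), W22), 0.6)
  expect_equal(marginal_fitness(1, matrix(0.7, 1, 1)), 0.7)
  expect_equal(mean_fitness(1, matrix(0.7, 1, 1)), 0.7)
  expect_equal(marginal_fitness(random_freq(4), matrix(0.3, 4, 4)),
               rep(0.3, 4))
  expect_equal(mean_fitness(c(0.5, 0.5), matrix(c(0.5, 1, 1, 0.5), 2)), 0.75)
  expect_error(marginal_fitness(c(0.5, 0.5), matrix(0.5, 3, 3)),
               "dimension mismatch")
})

test_that("selection follows the replicator recursion and fixes its equilibria", {
  expect_equal(selection_step(c(0.8, 0.2), W22),
               c(0.8 * 0.52, 0.2 * 0.92) / 0.6)
  # neutrality: constant viabilities leave frequencies unchanged
  set.seed(1)
  p <- random_freq(5)
  expect_equal(selection_step(p, matrix(0.4, 5, 5)), p)
  # symmetric overdominance: the even point is a fixed point
  expect_equal(selection_step(c(0.5, 0.5), matrix(c(0.5, 1, 1, 0.5), 2)),
               c(0.5, 0.5))
  expect_error(selection_step(1, viability_matrix(matrix(0, 1, 1))),
               "degenerate")
})

test_that("mutant introduction rescales residents and appends p0", {
  expect_equal(introduce_mutant(1, 5e-5), c(0.99995, 5e-5))
  expect_equal(introduce_mutant(1, 1 / (2 * 1e4)), c(0.99995, 5e-5))
  set.seed(3)
  for (i in 1:20) {
    p <- random_freq(sample(1:6, 1))
    p2 <- introduce_mutant(p, 5e-5)
    expect_equal(sum(p2), 1)
    expect_identical(length(p2), length(p) + 1L)
  }
  expect_error(introduce_mutant(1, 0), "p0")
  expect_error(introduce_mutant(1, 1), "p0")
})

test_that("the invasion predicate is equivalent to first-generation growth and survival", {
  set.seed(71)
  for (i in 1:1000) {
    W <- viability_matrix(random_sym_matrix(4))
    p3 <- random_freq(3)
    p4 <- introduce_mutant(p3, 5e-5)
    invades <- can_invade(p4, W)
    p_next <- selection_step(p4, W)
    # growth in one step ...
    expect_identical(p_next[4] > 5e-5, invades)
    # ... and retention through the strict extinction cut
    kept <- prune_extinct(p_next, W, threshold = 5e-5)$keep[4]
    expect_identical(kept, invades)
  }
  expect_error(can_invade(c(0.5, 0.5), W22, k = 3), "out of range")
})

test_that("drift sampling is unbiased multinomial on 2N gene copies", {
  expect_identical(drift_sample(1, 100), 1)
  N <- 500
  p <- c(0.2, 0.3, 0.5)
  set.seed(9)
  draws <- t(replicate(2000, drift_sample(p, N)))
  expect_true(all(abs(draws * 2 * N - round(draws * 2 * N)) < 1e-9))
  se_mean <- sqrt(p * (1 - p) / (2 * N)) / sqrt(nrow(draws))
  expect_true(all(abs(colMeans(draws) - p) < 4 * se_mean))
  v <- apply(draws, 2, stats::var)
  v_expected <- p * (1 - p) / (2 * N)
  expect_true(all(abs(v - v_expected) < 4 * v_expected * sqrt(2 / nrow(draws))))
})

test_that("extinction pruning applies the strict threshold and renormalizes", {
  W <- viability_matrix(random_sym_matrix(2))
  out <- prune_extinct(c(0.99996, 4e-5), W)
  expect_equal(out$p, 1)
  expect_identical(n_alleles(out$W), 1L)
  # the cut is strictly 'below': exactly 5e-5 survives
  out2 <- prune_extinct(c(0.99995, 5e-5), W)
  expect_identical(length(out2$p), 2L)
  # finite mode removes exact zeros only
  W3 <- viability_matrix(random_sym_matrix(3))
  out3 <- prune_extinct(c(0.7, 0.3, 0), W3, finite = TRUE)
  expect_equal(out3$p, c(0.7, 0.3))
  expect_identical(dim(out3$W$w), c(2L, 2L))
  expect_error(prune_extinct(c(0.3, 0.3, 0.4), W3, threshold = 0.5),
               "impossible state")
})

test_that("frequency vectors stay normalized across all operations", {
  set.seed(13)
  for (i in 1:200) {
    n <- sample(2:6, 1)
    W <- viability_matrix(random_sym_matrix(n))
    p <- random_freq(n)
    expect_lt(abs(sum(selection_step(p, W)) - 1), 1e-12)
    expect_lt(abs(sum(introduce_mutant(p, 5e-5)) - 1), 1e-12)
    expect_lt(abs(sum(drift_sample(p, 1000)) - 1), 1e-12)
    p_cut <- p
    p_cut[sample(n, 1)] <- 4e-5
    p_cut <- p_cut / sum(p_cut)
    expect_lt(abs(sum(prune_extinct(p_cut, W)$p) - 1), 1e-12)
  }
})

test_that("mean fitness never decreases under pure selection", {
  set.seed(29)
  for (i in 1:300) {
    n <- sample(2:6, 1)
    W <- viability_matrix(random_sym_matrix(n))
    p <- random_freq(n)
    for (s in 1:10) {
      wb <- mean_fitness(p, W)
      p <- selection_step(p, W)
      expect_gte(mean_fitness(p, W), wb - 1e-12)
    }
  }
})
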