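test_that("compiled and R engines produce the same realization under one seed", {
  configs <- list(
    sim_config(generations = 300),
    sim_config(generations = 150, decay = decay_model("constant", d = 0.995)),
    sim_config(fitness = "gendom", generations = 150,
               decay = decay_model("stochastic", mu = 0.999, sigma = 0.001)),
    sim_config(mode = "finite", N = 1e4, generations = 150,
               decay = decay_model("constant", d = 0.999))
  )
  for (cfg in configs) {
    a <- run_simulation(cfg, seed = 7, engine = "compiled")
    b <- run_simulation(cfg, seed = 7, engine = "R")
    expect_identical(a$census$labels, as.integer(b$census$labels))
    expect_identical(a$trajectory$n, b$trajectory$n)
    expect_identical(a$trajectory$n_c, b$trajectory$n_c)
    expect_equal(a$census$p, b$census$p, tolerance = 1e-10)
    expect_equal(a$census$W$w, b$census$W$w, tolerance = 1e-10)
    expect_equal(a$trajectory$mean_fitness, b$trajectory$mean_fitness,
                 tolerance = 1e-9)
    expect_identical(a$census$turnover, as.integer(b$census$turnover))
  }
})

test_that("zero-generation runs census the initial state", {
  sim <- run_simulation(sim_config(generations = 0), seed = 1)
  expect_identical(sim$census$n, 1L)
  expect_equal(sim$census$p, 1)
  expect_equal(sim$census$mean_fitness, 0.5)
  expect_identical(nrow(sim$trajectory), 1L)

  simg <- run_simulation(sim_config(fitness = "gendom", generations = 0),
                         seed = 23)
  set.seed(23)
  d <- runif(2)
  expect_equal(simg$census$mean_fitness, 2 / 3 * d[1] + 1 / 3 * d[2])
})

test_that("replicate batches are reproducible and reduce to single runs", {
  cfg <- sim_config(generations = 120)
  a <- run_replicates(cfg, replicates = 4, seed = 5)
  b <- run_replicates(cfg, replicates = 4, seed = 5)
  expect_identical(a$summary, b$summary)
  expect_identical(a$seeds, b$seeds)

  one <- run_replicates(cfg, replicates = 1, seed = 5)
  set.seed(5)
  spawned <- sample.int(2147483646L, 1)
  cfg1 <- cfg
  cfg1$record_trajectory <- FALSE
  single <- run_simulation(cfg1, seed = spawned)
  expect_equal(one$summary$n, single$census$n)
  expect_equal(one$summary$mean_fitness, single$census$mean_fitness)
  expect_equal(one$runs[[1]]$p, single$census$p)
})

test_that("allele bookkeeping: counts, commonness and fixation rarity", {
  sim <- run_simulation(sim_config(generations = 10000,
                                   decay = decay_model("constant", d = 0.999)),
                        seed = 42)
  tr <- sim$trajectory
  expect_identical(nrow(tr), 10001L)
  expect_true(all(tr$n_c <= tr$n))
  expect_true(all(tr$n >= 1))
  # fixation is rare: almost no single-allele generations after burn-in
  late <- tr$n[tr$generation > 100]
  expect_lt(mean(late == 1), 0.05)
  expect_identical(sim$census$n, length(sim$census$p))
  expect_true(all(sim$census$p > 0))
})

test_that("decay makes mean-fitness trajectories episodic, not monotone", {
  sim <- run_simulation(sim_config(generations = 10000,
                                   decay = decay_model("constant", d = 0.9999)),
                        seed = 8)
  dw <- diff(sim$trajectory$mean_fitness)
  expect_gt(sum(dw < 0), 0)
  expect_gt(sum(dw > 0), 0)
  # and plenty of genuine declines, not just rounding jitter
  expect_gt(sum(dw < -1e-6), 100)

  # without decay the engine's mean fitness climbs overall
  sim1 <- run_simulation(sim_config(generations = 10000), seed = 8)
  wb <- sim1$trajectory$mean_fitness
  expect_gt(wb[10001], 0.9)
  expect_gt(wb[10001], wb[1])
})

test_that("faster decay raises allele turnover", {
  wins <- 0L
  for (s in 1:50) {
    t1 <- run_simulation(sim_config(generations = 10000,
                                    record_trajectory = FALSE),
                         seed = 1000 + s)$census$turnover
    t2 <- run_simulation(sim_config(generations = 10000,
                                    decay = decay_model("constant", d = 0.995),
                                    record_trajectory = FALSE),
                         seed = 2000 + s)$census$turnover
    wins <- wins + (t2 > t1)
  }
  expect_gte(wins, 45L)
})

test_that("a generation counter advances one full cycle at a time", {
  cfg <- sim_config(generations = 50)
  set.seed(2)
  W <- init_viability("uniform")
  state <- list(p = 1, labels = 1L, generation = 0L, next_label = 2L,
                seen = TRUE, turnover = 1L)
  step <- run_generation(state, W, cfg)
  expect_identical(step$state$generation, 1L)
  expect_identical(step$state$next_label, 3L)
  expect_lt(abs(sum(step$state$p) - 1), 1e-12)
  expect_identical(length(step$state$p), n_alleles(step$W))
})
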