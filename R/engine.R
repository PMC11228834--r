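#' Simulation configuration
#'
#' Collects every parameter of a constructionist run: population-size mode,
#' fitness-generation method, decay model, run length, mutant initial
#' frequency, extinction and common-allele thresholds, and (optionally) the
#' master seed and replicate count used by [run_replicates()].
#'
#' Defaults follow the reference protocol: simulations run for \eqn{10^4}
#' generations starting from a single allele; mutants enter at
#' \eqn{p_0 = 5\times10^{-5}} (infinite mode) or \eqn{1/(2N)} (finite mode);
#' frequencies strictly below \eqn{5\times10^{-5}} are rounded to zero in
#' infinite mode; alleles at frequency > 0.01 are counted as common;
#' generalized dominance uses \eqn{\alpha = 1/3}.
#'
#' @param mode `"infinite"` or `"finite"`.
#' @param N diploid population size (finite mode only), e.g. 1e3 ... 1e6.
#' @param fitness mutant fitness generation method, `"uniform"` or `"gendom"`.
#' @param alpha generalized-dominance weight in \[0, 1/2).
#' @param decay a [decay_model()].
#' @param generations number of generations to simulate (>= 0).
#' @param census_at generation at which the census snapshot is taken
#'   (default: the final generation), recorded after the full cycle of that
#'   generation including extinction pruning.
#' @param p0 mutant initial frequency; defaults to 5e-5 (infinite) or 1/(2N).
#' @param extinction_threshold infinite-mode extinction cut.
#' @param common_threshold frequency above which an allele is common.
#' @param record_trajectory record per-generation `n`, `n_c`, mean fitness.
#' @param seed optional master seed.
#' @param replicates default replicate count for [run_replicates()].
#' @return An object of class `"rq_config"`.
#' @examples
#' sim_config(generations = 100)
#' sim_config(mode = "finite", N = 1e4, decay = decay_model("constant", d = 0.999))
#' @export
sim_config <- function(mode = c("infinite", "finite"), N = NULL,
                       fitness = c("uniform", "gendom"), alpha = 1 / 3,
                       decay = decay_model("none"),
                       generations = 10000L, census_at = NULL, p0 = NULL,
                       extinction_threshold = 5e-5, common_threshold = 0.01,
                       record_trajectory = TRUE, seed = NULL,
                       replicates = 1L) {
  mode <- match.arg(mode)
  fitness <- match.arg(fitness)
  stopifnot(inherits(decay, "decay_model"))
  if (mode == "finite") {
    if (is.null(N) || length(N) != 1 || is.na(N) || N < 1)
      stop("finite mode requires a positive population size 'N'")
    N <- as.numeric(N)
  } else {
    N <- NULL
  }
  if (fitness == "gendom") {
    if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha >= 0.5)
      stop("'alpha' must lie in [0, 1/2)")
  }
  generations <- as.integer(generations)
  if (is.na(generations) || generations < 0)
    stop("'generations' must be a non-negative integer")
  census_at <- as.integer(census_at %||% generations)
  if (is.na(census_at) || census_at < 0 || census_at > generations)
    stop("'census_at' must lie in [0, generations]")
  p0 <- p0 %||% (if (mode == "infinite") 5e-5 else 1 / (2 * N))
  if (p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly between 0 and 1")
  if (extinction_threshold <= 0 || extinction_threshold >= 1)
    stop("'extinction_threshold' must lie in (0, 1)")
  if (common_threshold <= 0 || common_threshold >= 1)
    stop("'common_threshold' must lie in (0, 1)")
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1)
    stop("'replicates' must be a positive integer")
  structure(
    list(mode = mode, N = N, fitness = fitness,
         alpha = if (fitness == "gendom") alpha,
         decay = decay, generations = generations, census_at = census_at,
         p0 = p0, extinction_threshold = extinction_threshold,
         common_threshold = common_threshold,
         record_trajectory = isTRUE(record_trajectory),
         seed = if (!is.null(seed)) as.integer(seed),
         replicates = replicates),
    class = "rq_config"
  )
}

#' Advance a population by one full generation cycle
#'
#' Applies, in order: (1) environmental decay of all extant viabilities (and
#' primary effects under constant decay with generalized dominance); (2)
#' creation of exactly one novel mutant -- fresh viabilities via
#' [add_mutant()], introduction at frequency `p0`; (3) deterministic viability
#' selection; (4) multinomial drift when finite; (5) extinction pruning with
#' renormalization.  Decay precedes mutant creation, so a mutant's freshly
#' drawn viabilities are not decayed in its birth generation -- old alleles
#' deteriorate while newcomers arrive undecayed.
#'
#' This is the reference R implementation of the cycle; [run_simulation()]
#' runs the same cycle (consuming the RNG stream in the identical order) in
#' compiled code.
#'
#' @param state a list with elements `p` (frequencies), `labels` (allele birth
#'   indices), `generation`, `next_label`, `seen` (logical, allele has ever
#'   been common) and `turnover` (count of alleles ever common), as produced
#'   by [run_simulation()] internals or assembled by hand.
#' @param W a [viability_matrix()] for the extant alleles.
#' @param config an [sim_config()] object.
#' @return A list `list(state = , W = )` after one generation.
#' @export
run_generation <- function(state, W, config) {
  stopifnot(inherits(config, "rq_config"))
  finite <- config$mode == "finite"
  W <- apply_decay(W, config$decay)
  W <- add_mutant(W)
  p <- introduce_mutant(state$p, config$p0)
  p <- selection_step(p, W)
  if (finite) p <- drift_sample(p, config$N)
  pr <- prune_extinct(p, W, threshold = config$extinction_threshold,
                      finite = finite)
  labels <- c(state$labels, state$next_label)[pr$keep]
  seen <- c(state$seen, FALSE)[pr$keep]
  newly <- !seen & pr$p > config$common_threshold
  seen[newly] <- TRUE
  state$p <- pr$p
  state$labels <- labels
  state$seen <- seen
  state$turnover <- state$turnover + sum(newly)
  state$next_label <- state$next_label + 1L
  state$generation <- state$generation + 1L
  list(state = state, W = pr$W)
}

.decay_code <- function(decay) {
  switch(decay$kind, none = 0L, constant = 1L, stochastic = 2L)
}

.census_build <- function(p, labels, W, wbar, turnover, common_threshold,
                          replicate = 1L, seed = NA_integer_) {
  n <- length(p)
  nc <- sum(p > common_threshold)
  loc <- if (nc >= 1) location_statistic(p, common_threshold) else
    list(I = NA_real_, n_c = 0L)
  list(replicate = replicate, seed = seed,
       p = p, labels = labels, W = W,
       n = n, n_c = nc, mean_fitness = wbar,
       mean_homozygote = mean(diag(W$w)),
       mean_heterozygote = if (n > 1) mean(W$w[upper.tri(W$w)]) else NA_real_,
       I = loc$I, turnover = turnover)
}

#' Run one constructionist simulation
#'
#' Starts from a single allele (uniform method: \eqn{w_{11} = 0.5};
#' generalized dominance: \eqn{w_{11} = 2\alpha X_1 + (1-2\alpha) Y_{11}} from
#' fresh uniform draws) and iterates the [run_generation()] cycle for
#' `config$generations` generations, recording the per-generation trajectory
#' (total alleles `n`, common alleles `n_c`, mean fitness) when requested and
#' a census snapshot at `config$census_at`.
#'
#' The census and trajectory count every allele still present (frequency
#' > 0) after the generation's selection step -- and, in finite mode, after
#' drift, where an allele sampled to zero copies is extinct immediately.  In
#' infinite-population mode the extinction sweep that rounds frequencies
#' strictly below `extinction_threshold` to zero is applied *after*
#' recording, i.e. it is the first thing that acts on those frequencies
#' going into the next generation; a census-generation mutant that failed to
#' invade is therefore still counted, at its sub-threshold frequency.
#'
#' The default engine is compiled (C++); `engine = "R"` runs the pure-R cycle.
#' Both consume R's RNG stream in the same order, so with equal seeds they
#' produce the same realization (up to floating-point accumulation order).
#'
#' @param config an [sim_config()] object.
#' @param seed integer seed for this run (`NULL` to use the current RNG
#'   state).
#' @param engine `"compiled"` or `"R"`.
#' @param verbose log progress every 1000 generations to stderr.
#' @return An object of class `"rq_sim"`: a list with elements `config`,
#'   `seed`, `census` (frequencies, labels, viability matrix, `n`, `n_c`,
#'   mean fitness, homozygote/heterozygote viability means, evenness `I`,
#'   allele turnover) and `trajectory` (a data frame, or `NULL`).
#' @examples
#' sim <- run_simulation(sim_config(generations = 200), seed = 1)
#' sim$census$n
#' @export
run_simulation <- function(config, seed = config$seed,
                           engine = c("compiled", "R"), verbose = FALSE) {
  stopifnot(inherits(config, "rq_config"))
  engine <- match.arg(engine)
  if (!is.null(seed)) set.seed(seed)
  gendom <- config$fitness == "gendom"
  if (engine == "compiled") {
    res <- run_sim_cpp(
      config$mode == "infinite", config$N %||% 0,
      gendom, config$alpha %||% 0,
      .decay_code(config$decay), config$decay$d %||% 1,
      config$decay$mu %||% 0, config$decay$sigma %||% 1,
      config$generations, config$census_at, config$p0,
      config$extinction_threshold, config$common_threshold,
      config$record_trajectory, isTRUE(verbose)
    )
    cen <- res$census
    W <- viability_matrix(cen$w, X = cen$X,
                          alpha = if (gendom) config$alpha)
    census <- .census_build(cen$p, cen$labels, W, cen$mean_fitness,
                            cen$turnover, config$common_threshold,
                            seed = seed %||% NA_integer_)
    traj <- res$trajectory
  } else {
    finite <- config$mode == "finite"
    W <- init_viability(config$fitness, config$alpha %||% (1 / 3))
    state <- list(p = 1, labels = 1L, generation = 0L, next_label = 2L,
                  seen = 1 > config$common_threshold, turnover = 0L)
    state$turnover <- sum(state$seen)
    traj <- if (config$record_trajectory)
      matrix(NA_real_, config$generations + 1L, 3L)
    snap <- NULL
    record <- function(t) {
      if (!is.null(traj))
        traj[t + 1L, ] <<- c(length(state$p),
                             sum(state$p > config$common_threshold),
                             mean_fitness(state$p, W))
    }
    record(0L)
    if (config$census_at == 0L) snap <- list(state = state, W = W)
    for (t in seq_len(config$generations)) {
      W <- apply_decay(W, config$decay)
      W <- add_mutant(W)
      p <- introduce_mutant(state$p, config$p0)
      p <- selection_step(p, W)
      keep <- rep(TRUE, length(p))
      if (finite) {
        p <- drift_sample(p, config$N)
        pr <- prune_extinct(p, W, finite = TRUE)
        p <- pr$p
        W <- pr$W
        keep <- pr$keep
      }
      seen <- c(state$seen, FALSE)[keep]
      newly <- !seen & p > config$common_threshold
      seen[newly] <- TRUE
      state$p <- p
      state$labels <- c(state$labels, state$next_label)[keep]
      state$seen <- seen
      state$turnover <- state$turnover + sum(newly)
      state$next_label <- state$next_label + 1L
      state$generation <- state$generation + 1L
      # trajectory and census see every allele still present (p > 0); the
      # infinite-mode sub-threshold sweep acts afterwards, going into the
      # next generation
      record(t)
      if (t == config$census_at) snap <- list(state = state, W = W)
      if (!finite) {
        sw <- prune_extinct(state$p, W,
                            threshold = config$extinction_threshold)
        W <- sw$W
        state$p <- sw$p
        state$labels <- state$labels[sw$keep]
        state$seen <- state$seen[sw$keep]
      }
      if (verbose && t %% 1000L == 0L)
        message("generation ", t, ": n=", length(state$p))
    }
    if (is.null(snap)) snap <- list(state = state, W = W)
    census <- .census_build(snap$state$p, snap$state$labels, snap$W,
                            mean_fitness(snap$state$p, snap$W),
                            snap$state$turnover, config$common_threshold,
                            seed = seed %||% NA_integer_)
  }
  trajectory <- NULL
  if (config$record_trajectory && !is.null(traj)) {
    trajectory <- data.frame(generation = 0:config$generations,
                             n = as.integer(traj[, 1]),
                             n_c = as.integer(traj[, 2]),
                             mean_fitness = traj[, 3])
  }
  structure(list(config = config, seed = seed, engine = engine,
                 census = census, trajectory = trajectory),
            class = "rq_sim")
}

#' Run a batch of replicate simulations
#'
#' Runs `replicates` independent simulations differing only in their seeds,
#' which are spawned deterministically from the master seed, and collects the
#' per-replicate censuses.  Identical `(config, seed)` gives identical output.
#' Trajectories are not recorded in batch mode.
#'
#' @param config an [sim_config()] object.
#' @param replicates number of replicate runs.
#' @param seed master seed.
#' @param engine `"compiled"` or `"R"`.
#' @return An object of class `"rq_census"`: a list with elements `summary`
#'   (data frame: one row per replicate with `n`, `n_c`, `mean_fitness`,
#'   `mean_homozygote`, `mean_heterozygote`, `I`, `turnover`), `runs` (list of
#'   per-replicate census records including frequencies and viability
#'   matrices), `config`, `master_seed` and `seeds`.
#' @examples
#' cb <- run_replicates(sim_config(generations = 100), replicates = 5, seed = 1)
#' cb$summary$n
#' @export
run_replicates <- function(config, replicates = config$replicates,
                           seed = config$seed %||% 1L,
                           engine = c("compiled", "R")) {
  stopifnot(inherits(config, "rq_config"))
  engine <- match.arg(engine)
  replicates <- as.integer(replicates)
  if (is.na(replicates) || replicates < 1)
    stop("'replicates' must be a positive integer")
  config$record_trajectory <- FALSE
  set.seed(seed)
  seeds <- sample.int(2147483646L, replicates)
  runs <- vector("list", replicates)
  for (r in seq_len(replicates)) {
    sim <- run_simulation(config, seed = seeds[r], engine = engine)
    cen <- sim$census
    cen$replicate <- r
    cen$seed <- seeds[r]
    runs[[r]] <- cen
  }
  summary <- data.frame(
    replicate = seq_len(replicates),
    seed = seeds,
    n = vapply(runs, `[[`, integer(1), "n"),
    n_c = vapply(runs, function(x) as.integer(x$n_c), integer(1)),
    mean_fitness = vapply(runs, `[[`, numeric(1), "mean_fitness"),
    mean_homozygote = vapply(runs, `[[`, numeric(1), "mean_homozygote"),
    mean_heterozygote = vapply(runs, `[[`, numeric(1), "mean_heterozygote"),
    I = vapply(runs, `[[`, numeric(1), "I"),
    turnover = vapply(runs, function(x) as.integer(x$turnover), integer(1))
  )
  structure(list(summary = summary, runs = runs, config = config,
                 master_seed = as.integer(seed), seeds = seeds),
            class = "rq_census")
}
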