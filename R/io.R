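.num <- function(x) sprintf("%.17g", x)

.manifest_lines <- function(config, master_seed = NULL, seeds = NULL) {
  dl <- config$decay
  decay_txt <- switch(dl$kind,
    none = "none",
    constant = paste0("constant d=", .num(dl$d)),
    stochastic = paste0("stochastic mu=", .num(dl$mu), " sigma=", .num(dl$sigma)))
  c(paste0("# generated_by: redqueen ", as.character(packageVersion("redqueen"))),
    paste0("# mode: ", config$mode),
    if (!is.null(config$N)) paste0("# N: ", .num(config$N)),
    paste0("# fitness: ", config$fitness),
    if (!is.null(config$alpha)) paste0("# alpha: ", .num(config$alpha)),
    paste0("# decay: ", decay_txt),
    paste0("# generations: ", config$generations),
    paste0("# census_at: ", config$census_at),
    paste0("# p0: ", .num(config$p0)),
    paste0("# extinction_threshold: ", .num(config$extinction_threshold)),
    paste0("# common_threshold: ", .num(config$common_threshold)),
    if (!is.null(master_seed)) paste0("# master_seed: ", master_seed),
    if (!is.null(seeds)) paste0("# seeds: ", paste(seeds, collapse = ",")))
}

.write_tsv <- function(df, path, manifest) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(manifest, con)
  writeLines(paste(names(df), collapse = "\t"), con)
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], .num)
  write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

#' Read a simulation configuration from a YAML file
#'
#' Top-level keys: `mode`, `N`, `fitness`, `alpha`, `decay` (a mapping with
#' keys `kind` and, as appropriate, `d` or `mu`/`sigma`), `generations`,
#' `census_at`, `p0`, `extinction_threshold`, `common_threshold`,
#' `record_trajectory`, `seed`, `replicates`.  Unknown keys are rejected by
#' name; omitted keys take the reference defaults (see [sim_config()]).
#'
#' @param path path to a YAML configuration file.
#' @return An [sim_config()] object.
#' @examples
#' f <- tempfile(fileext = ".yaml")
#' writeLines(c("mode: infinite", "decay:", "  kind: constant", "  d: 0.999"), f)
#' parse_config(f)
#' @export
parse_config <- function(path) {
  if (!file.exists(path))
    stop("config file not found: ", path)
  raw <- yaml::read_yaml(path)
  if (!is.list(raw))
    stop("config file must contain a key-value mapping")
  # YAML 1.1 resolves a bare N/n key to a boolean; map it back
  names(raw)[names(raw) %in% c("FALSE", "F")] <- "N"
  allowed <- c("mode", "N", "fitness", "alpha", "decay", "generations",
               "census_at", "p0", "extinction_threshold", "common_threshold",
               "record_trajectory", "seed", "replicates")
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  decay <- decay_model("none")
  if (!is.null(raw$decay)) {
    dk <- raw$decay
    if (!is.list(dk) || is.null(dk$kind))
      stop("'decay' must be a mapping with a 'kind' key")
    dk_allowed <- c("kind", "d", "mu", "sigma")
    dk_unknown <- setdiff(names(dk), dk_allowed)
    if (length(dk_unknown))
      stop("unknown decay keys: ", paste(dk_unknown, collapse = ", "))
    decay <- switch(as.character(dk$kind),
      none = decay_model("none"),
      constant = decay_model("constant", d = dk$d %||% 1),
      stochastic = decay_model("stochastic", mu = dk$mu %||% 0.999,
                               sigma = dk$sigma %||% 0.001),
      stop("unknown decay kind: ", dk$kind))
  }
  args <- list(decay = decay)
  for (key in c("mode", "N", "fitness", "alpha", "generations", "census_at",
                "p0", "extinction_threshold", "common_threshold",
                "record_trajectory", "seed", "replicates"))
    if (!is.null(raw[[key]])) args[[key]] <- raw[[key]]
  do.call(sim_config, args)
}

#' Write and read census tables
#'
#' `write_census()` serializes a [run_replicates()] batch as two TSV files:
#' `<path>_summary.tsv` with one row per replicate, and `<path>_alleles.tsv`
#' with one row per (replicate, allele) carrying the allele's birth label,
#' frequency, primary effect (generalized dominance only) and its row of the
#' viability matrix (comma-separated, in extant-allele order).  Both files
#' start with `#`-prefixed manifest lines echoing the configuration and
#' seeds, and all numbers are serialized at full precision (17 significant
#' digits), so a round trip is exact.  `read_census()` reconstructs the
#' summary table and the per-replicate frequency vectors and viability
#' matrices.
#'
#' @param x an `"rq_census"` object.
#' @param path output path prefix (for `write_census`) or the prefix used at
#'   write time (for `read_census`).
#' @return `write_census()` returns the two file paths invisibly;
#'   `read_census()` returns a list with elements `summary` (data frame) and
#'   `runs` (list with `p`, `labels`, `w`, `X` per replicate).
#' @examples
#' cb <- run_replicates(sim_config(generations = 50), replicates = 2, seed = 1)
#' pre <- file.path(tempdir(), "census-demo")
#' write_census(cb, pre)
#' cen <- read_census(pre)
#' cen$summary$n
#' @export
write_census <- function(x, path) {
  stopifnot(inherits(x, "rq_census"))
  manifest <- .manifest_lines(x$config, x$master_seed, x$seeds)
  f_sum <- paste0(path, "_summary.tsv")
  f_all <- paste0(path, "_alleles.tsv")
  .write_tsv(x$summary, f_sum, manifest)
  rows <- lapply(x$runs, function(cen) {
    n <- cen$n
    data.frame(
      replicate = cen$replicate,
      allele = cen$labels,
      frequency = cen$p,
      X = if (!is.null(cen$W$X)) cen$W$X else NA_real_,
      w = vapply(seq_len(n),
                 function(i) paste(.num(cen$W$w[i, ]), collapse = ","),
                 character(1)))
  })
  .write_tsv(do.call(rbind, rows), f_all, manifest)
  invisible(c(f_sum, f_all))
}

#' @rdname write_census
#' @export
read_census <- function(path) {
  f_sum <- paste0(path, "_summary.tsv")
  f_all <- paste0(path, "_alleles.tsv")
  summary <- read.table(f_sum, header = TRUE, sep = "\t",
                        comment.char = "#")
  alleles <- read.table(f_all, header = TRUE, sep = "\t",
                        comment.char = "#",
                        colClasses = c("integer", "integer", "numeric",
                                       "numeric", "character"))
  runs <- lapply(split(alleles, alleles$replicate), function(df) {
    w <- do.call(rbind, lapply(strsplit(df$w, ","), as.numeric))
    list(p = df$frequency, labels = df$allele, w = unname(w),
         X = if (all(is.na(df$X))) NULL else df$X)
  })
  list(summary = summary, runs = unname(runs))
}

#' Write and read an exemplar trajectory
#'
#' One TSV with columns `generation`, `n`, `n_c`, `mean_fitness`, prefixed by
#' `#` manifest lines.
#'
#' @param x an `"rq_sim"` object with a recorded trajectory.
#' @param path output file path (for `write_trajectory`) or input path (for
#'   `read_trajectory`).
#' @return `write_trajectory()` returns `path` invisibly; `read_trajectory()`
#'   returns the trajectory data frame.
#' @examples
#' sim <- run_simulation(sim_config(generations = 50), seed = 1)
#' f <- tempfile(fileext = ".tsv")
#' write_trajectory(sim, f)
#' head(read_trajectory(f))
#' @export
write_trajectory <- function(x, path) {
  stopifnot(inherits(x, "rq_sim"))
  if (is.null(x$trajectory))
    stop("this run recorded no trajectory")
  manifest <- c(.manifest_lines(x$config),
                if (!is.null(x$seed)) paste0("# seed: ", x$seed))
  .write_tsv(x$trajectory, path, manifest)
}

#' @rdname write_trajectory
#' @export
read_trajectory <- function(path) {
  read.table(path, header = TRUE, sep = "\t", comment.char = "#")
}

#' Small deterministic fixtures for tests and examples
#'
#' - `"initial"`: the canonical single-allele start, \eqn{w_{11} = 0.5};
#' - `"overdominant-2"`: \eqn{w_{12} = 1} above both homozygotes (0.5), a
#'   feasible and stable two-allele polymorphism;
#' - `"underdominant-2"`: the reverse, feasible but unstable;
#' - `"random-3"`: a reproducible random symmetric 3 x 3 viability set.
#'
#' @param kind fixture name.
#' @param seed seed used by `"random-3"`.
#' @return A [viability_matrix()].
#' @examples
#' fixture_matrix("overdominant-2")
#' @export
fixture_matrix <- function(kind = c("initial", "overdominant-2",
                                    "underdominant-2", "random-3"),
                           seed = 1L) {
  kind <- match.arg(kind)
  switch(kind,
    "initial" = viability_matrix(matrix(0.5, 1, 1)),
    "overdominant-2" = viability_matrix(matrix(c(0.5, 1, 1, 0.5), 2)),
    "underdominant-2" = viability_matrix(matrix(c(1, 0.5, 0.5, 1), 2)),
    "random-3" = {
      set.seed(seed)
      w <- matrix(0, 3, 3)
      w[upper.tri(w, diag = TRUE)] <- runif(6)
      w[lower.tri(w)] <- t(w)[lower.tri(w)]
      viability_matrix(w)
    })
}
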