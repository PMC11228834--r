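#' @export
print.viability_matrix <- function(x, ...) {
  n <- nrow(x$w)
  cat("Viability matrix:", n, if (n == 1) "allele," else "alleles,",
      x$method, "method\n")
  print(signif(x$w, 4))
  if (!is.null(x$X)) {
    cat("primary effects X (alpha =", format(x$alpha, digits = 4), "):\n")
    print(signif(x$X, 4))
  }
  invisible(x)
}

#' @export
print.decay_model <- function(x, ...) {
  cat("Decay model:",
      switch(x$kind,
        none = "none (constant environment)",
        constant = paste0("constant, d = ", format(x$d)),
        stochastic = paste0("stochastic, d_ij ~ N(", format(x$mu), ", ",
                            format(x$sigma), "^2)")),
      "\n")
  invisible(x)
}

#' @export
print.rq_config <- function(x, ...) {
  cat("Simulation configuration\n")
  cat("  population:  ",
      if (x$mode == "infinite") "infinite"
      else paste0("finite, N = ", format(x$N, big.mark = ",")), "\n", sep = "")
  cat("  fitnesses:   ", if (x$fitness == "uniform") "independent U[0,1]"
      else paste0("generalized dominance, alpha = ",
                  format(x$alpha, digits = 4)), "\n", sep = "")
  cat("  decay:       ", switch(x$decay$kind,
        none = "none",
        constant = paste0("constant, d = ", format(x$decay$d)),
        stochastic = paste0("stochastic, N(", format(x$decay$mu), ", ",
                            format(x$decay$sigma), "^2)")), "\n", sep = "")
  cat("  generations: ", x$generations, " (census at ", x$census_at, ")\n",
      sep = "")
  cat("  mutant p0:   ", format(x$p0), "; extinction cut ",
      format(x$extinction_threshold), "; common cut ",
      format(x$common_threshold), "\n", sep = "")
  invisible(x)
}

#' @export
print.rq_sim <- function(x, ...) {
  cen <- x$census
  cat("Constructionist simulation (", x$config$generations,
      " generations, ", x$config$mode, " population)\n", sep = "")
  if (!is.null(x$seed)) cat("  seed:", x$seed, "\n")
  cat("  census at generation ", x$config$census_at, ": n = ", cen$n,
      ", n_c = ", cen$n_c, ", mean fitness = ",
      format(cen$mean_fitness, digits = 4), "\n", sep = "")
  cat("  allele turnover (ever common):", cen$turnover, "\n")
  invisible(x)
}

#' @export
summary.rq_sim <- function(object, ...) {
  cen <- object$census
  print(object)
  cat("  frequencies (by birth order):\n")
  print(data.frame(allele = cen$labels, frequency = signif(cen$p, 4),
                   homozygote_viability = signif(diag(cen$W$w), 4)),
        row.names = FALSE)
  cat("  mean homozygote viability:  ",
      format(cen$mean_homozygote, digits = 4), "\n")
  cat("  mean heterozygote viability:",
      format(cen$mean_heterozygote, digits = 4), "\n")
  cat("  evenness I of common alleles:", format(cen$I, digits = 4), "\n")
  invisible(object)
}

#' Plot a simulated trajectory
#'
#' Total and common allele numbers on the left axis, mean fitness (in
#' \[0, 1\]) on the right axis, against generation.
#'
#' @param x an `"rq_sim"` object with a recorded trajectory.
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.rq_sim <- function(x, ...) {
  tr <- x$trajectory
  if (is.null(tr))
    stop("this run recorded no trajectory")
  op <- par(mar = c(4, 4, 2, 4))
  on.exit(par(op))
  plot(tr$generation, tr$n, type = "l", col = "magenta",
       xlab = "generation", ylab = "number of alleles",
       ylim = c(0, max(tr$n)), ...)
  lines(tr$generation, tr$n_c, col = "pink3")
  par(new = TRUE)
  plot(tr$generation, tr$mean_fitness, type = "l", col = "blue",
       axes = FALSE, xlab = "", ylab = "", ylim = c(0, 1))
  axis(4)
  mtext("mean fitness", side = 4, line = 2.5)
  legend("bottomright", bty = "n", lty = 1,
         col = c("magenta", "pink3", "blue"),
         legend = c("n (total)", "n_c (common)", "mean fitness"))
  invisible(x)
}

#' @export
print.rq_census <- function(x, ...) {
  cat("Replicate census batch: ", nrow(x$summary), " runs, ",
      x$config$mode, " population, ", x$config$generations,
      " generations\n", sep = "")
  cat("  master seed:", x$master_seed, "\n")
  cat("  mean n = ", format(mean(x$summary$n), digits = 4),
      ", mean n_c = ", format(mean(x$summary$n_c), digits = 4),
      ", mean fitness = ",
      format(mean(x$summary$mean_fitness), digits = 4), "\n", sep = "")
  invisible(x)
}

#' @export
summary.rq_census <- function(object, ...) {
  summarize_census(object)
}

#' Plot a replicate census batch
#'
#' Four panels: frequency distributions of the total and common allele
#' numbers, mean fitness against total allele number, and the
#' fitness-structure scatter (mean homozygote vs mean heterozygote
#' viability).
#'
#' @param x an `"rq_census"` object.
#' @param ... ignored.
#' @return `x`, invisibly.
#' @export
plot.rq_census <- function(x, ...) {
  df <- x$summary
  op <- par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(par(op))
  barplot(table(df$n), xlab = "n (total alleles)", ylab = "runs",
          main = "total alleles")
  barplot(table(df$n_c), xlab = "n_c (common alleles)", ylab = "runs",
          main = "common alleles")
  plot(df$n, df$mean_fitness, xlab = "n", ylab = "mean fitness",
       main = "fitness by allele number")
  cc <- stats::complete.cases(df$mean_homozygote, df$mean_heterozygote)
  plot(df$mean_homozygote[cc], df$mean_heterozygote[cc],
       xlab = "mean homozygote viability",
       ylab = "mean heterozygote viability",
       main = "fitness structure")
  invisible(x)
}

#' @export
print.census_summary <- function(x, ...) {
  cat("Census summary over", x$replicates, "replicates\n")
  cat("  total alleles n:   mean", format(x$mean_n, digits = 4), "\n")
  print(x$n_table)
  cat("  common alleles n_c: mean", format(x$mean_nc, digits = 4), "\n")
  print(x$nc_table)
  cat("  homozygote-heterozygote viability-mean correlation:",
      format(x$homo_het_correlation, digits = 4), "\n")
  invisible(x)
}

#' @export
print.equilibrium_result <- function(x, ...) {
  cat("Interior equilibrium of a", length(x$p_star), "allele viability set\n")
  cat("  p* =", paste(signif(x$p_star, 4), collapse = ", "), "\n")
  cat("  eigenvalues:", paste(signif(x$eigenvalues, 4), collapse = ", "),
      "\n")
  cat("  feasible:", x$feasible, " stable:", x$stable, "\n")
  invisible(x)
}

#' @export
print.set_scan <- function(x, ...) {
  cat("Random viability-set scan: n =", x$n, "alleles,",
      format(x$num_sets, big.mark = ","), "sets\n")
  cat("  feasible and stable:", x$count,
      sprintf("(proportion %.3g)", x$proportion), "\n")
  invisible(x)
}
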