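#' Indices of common alleles
#'
#' An allele is *common* when its frequency strictly exceeds the threshold
#' (canonically 0.01).
#'
#' @param p numeric vector of allele frequencies.
#' @param threshold commonness cut.
#' @return Integer vector of indices of the common alleles.
#' @examples
#' common_alleles(c(0.5, 0.49, 0.009, 0.001))
#' @export
common_alleles <- function(p, threshold = 0.01) {
  which(p > threshold)
}

#' Evenness of a polymorphism: squared distance to the simplex centroid
#'
#' Measures where a polymorphism sits in the state space of possible
#' common-allele frequencies: restrict to the common alleles, renormalize
#' their frequencies to sum to 1, and compute
#' \deqn{I = \sum_{c=1}^{n_c} \left(p_c - \frac{1}{n_c}\right)^2,}
#' the squared Euclidean distance to the centroid of the
#' \eqn{(n_c - 1)}-simplex.  Rare alleles are excluded because they drag the
#' location toward the edges of state space without being an important part
#' of the polymorphism.  \eqn{I = 0} means perfectly even common-allele
#' frequencies; larger values mean more uneven ones, with supremum
#' \eqn{(n_c - 1)/n_c}.
#'
#' @inheritParams common_alleles
#' @return A list with elements `I`, `n_c` and `p_common` (the renormalized
#'   common-allele frequencies).
#' @examples
#' location_statistic(c(0.25, 0.25, 0.25, 0.25))$I # 0
#' location_statistic(c(0.7, 0.1, 0.1, 0.1))$I     # 0.27
#' @export
location_statistic <- function(p, threshold = 0.01) {
  idx <- common_alleles(p, threshold)
  if (length(idx) == 0)
    stop("no common alleles: cannot locate the polymorphism")
  pc <- p[idx] / sum(p[idx])
  nc <- length(idx)
  list(I = sum((pc - 1 / nc)^2), n_c = nc, p_common = pc)
}

#' Sample random allele frequencies by the broken-stick method
#'
#' Draws \eqn{n_c - 1} uniform break points on \[0, 1\]; the frequencies are
#' the gaps between adjacent break points.  This samples uniformly from the
#' \eqn{(n_c - 1)}-dimensional simplex and is the null model for
#' "random allele frequencies constrained to add to one".
#'
#' @param n_c number of alleles (>= 1).
#' @return Numeric vector of `n_c` non-negative frequencies summing to 1.
#' @examples
#' set.seed(1)
#' broken_stick_sample(4)
#' @export
broken_stick_sample <- function(n_c) {
  n_c <- as.integer(n_c)
  if (is.na(n_c) || n_c < 1)
    stop("'n_c' must be a positive integer")
  if (n_c == 1) return(1)
  diff(c(0, sort(runif(n_c - 1)), 1))
}

#' Null distribution of the evenness statistic I
#'
#' Monte Carlo distribution of [location_statistic()]'s `I` under the
#' broken-stick null: frequencies drawn uniformly from the simplex, all
#' treated as common (no threshold, no renormalization needed).
#'
#' @param n_c number of alleles (>= 2).
#' @param samples number of broken-stick draws.
#' @return Numeric vector of `samples` values of `I`.
#' @examples
#' set.seed(1)
#' mean(null_I_distribution(2, 1e4)) # about 1/6
#' @export
null_I_distribution <- function(n_c, samples = 1e4) {
  n_c <- as.integer(n_c)
  if (is.na(n_c) || n_c < 2)
    stop("'n_c' must be an integer >= 2")
  samples <- as.integer(samples)
  if (is.na(samples) || samples < 1)
    stop("'samples' must be a positive integer")
  b <- matrix(runif(samples * (n_c - 1)), samples)
  if (n_c > 2)
    b <- t(apply(b, 1, sort))
  p <- cbind(b, 1) - cbind(0, b)
  rowSums((p - 1 / n_c)^2)
}

#' Summarize a batch of census records
#'
#' Collates the across-replicate picture of a [run_replicates()] batch:
#' frequency tables and means of the total (`n`) and common (`n_c`) allele
#' numbers, the mean fitness binned by `n` and by `n_c`, and the
#' fitness-structure summary -- per-replicate mean homozygote viability
#' (mean of the extant \eqn{w_{ii}}), mean heterozygote viability (unweighted
#' mean over distinct extant pairs \eqn{w_{ij}, i < j}) and their Pearson
#' correlation across replicates.
#'
#' @param x an `"rq_census"` object from [run_replicates()], or its `summary`
#'   data frame (columns `n`, `n_c`, `mean_fitness`, `mean_homozygote`,
#'   `mean_heterozygote`).
#' @return An object of class `"census_summary"`: a list with elements
#'   `n_table`, `nc_table`, `mean_n`, `mean_nc`, `wbar_by_n`, `wbar_by_nc`,
#'   `fitness_structure` (data frame of the two viability means) and
#'   `homo_het_correlation`.
#' @examples
#' cb <- run_replicates(sim_config(generations = 100), replicates = 5, seed = 1)
#' summarize_census(cb)
#' @export
summarize_census <- function(x) {
  df <- if (inherits(x, "rq_census")) x$summary else as.data.frame(x)
  if (nrow(df) == 0)
    stop("empty census: nothing to summarize")
  needed <- c("n", "n_c", "mean_fitness", "mean_homozygote",
              "mean_heterozygote")
  missing <- setdiff(needed, names(df))
  if (length(missing))
    stop("census table lacks columns: ", paste(missing, collapse = ", "))
  wbar_by <- function(key) {
    v <- tapply(df$mean_fitness, df[[key]], mean)
    data.frame(group = as.integer(names(v)), mean_fitness = as.numeric(v))
  }
  fs <- df[, c("mean_homozygote", "mean_heterozygote")]
  cc <- stats::complete.cases(fs)
  r <- if (sum(cc) >= 3 && stats::sd(fs$mean_homozygote[cc]) > 0 &&
           stats::sd(fs$mean_heterozygote[cc]) > 0)
    cor(fs$mean_homozygote[cc], fs$mean_heterozygote[cc])
  else NA_real_
  structure(
    list(replicates = nrow(df),
         n_table = table(df$n), nc_table = table(df$n_c),
         mean_n = mean(df$n), mean_nc = mean(df$n_c),
         wbar_by_n = wbar_by("n"), wbar_by_nc = wbar_by("n_c"),
         fitness_structure = fs,
         homo_het_correlation = r),
    class = "census_summary"
  )
}
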