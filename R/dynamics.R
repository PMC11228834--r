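#' @keywords internal
#' @noRd
.wmat <- function(W) {
  if (inherits(W, "viability_matrix")) W$w else unname(as.matrix(W))
}

.check_dims <- function(p, w) {
  if (length(p) != nrow(w))
    stop("dimension mismatch: ", length(p), " frequencies vs ",
         nrow(w), " alleles in the viability matrix")
}

#' Marginal fitnesses of the extant alleles
#'
#' The marginal fitness of allele \eqn{A_i} is its mean viability across the
#' genotype contexts it currently occurs in,
#' \eqn{m_i = \sum_j w_{ij} p_j}.
#'
#' @param p numeric vector of allele frequencies (non-negative, summing to 1).
#' @param W a [viability_matrix()] or a plain symmetric matrix.
#' @return Numeric vector of marginal fitnesses, one per allele.
#' @examples
#' marginal_fitness(c(0.8, 0.2), matrix(c(0.4, 1, 1, 0.6), 2))
#' @export
marginal_fitness <- function(p, W) {
  w <- .wmat(W)
  .check_dims(p, w)
  drop(w %*% p)
}

#' Population mean fitness
#'
#' \eqn{\bar w = \sum_i p_i m_i = p^T W p}, the average viability of the
#' population.
#'
#' @inheritParams marginal_fitness
#' @return The mean fitness, a scalar.
#' @examples
#' mean_fitness(c(0.8, 0.2), matrix(c(0.4, 1, 1, 0.6), 2))
#' @export
mean_fitness <- function(p, W) {
  sum(p * marginal_fitness(p, W))
}

#' One deterministic generation of viability selection
#'
#' Iterates the standard single-locus recursion
#' \deqn{\bar w \, p_i' = p_i \sum_j w_{ij} p_j,}
#' i.e. \eqn{p_i' = p_i m_i / \bar w}.  The output sums to 1 by construction.
#'
#' @inheritParams marginal_fitness
#' @return Updated frequency vector.
#' @examples
#' selection_step(c(0.8, 0.2), matrix(c(0.4, 1, 1, 0.6), 2))
#' @export
selection_step <- function(p, W) {
  m <- marginal_fitness(p, W)
  wbar <- sum(p * m)
  if (!is.finite(wbar) || wbar <= 0)
    stop("degenerate population: mean fitness is zero")
  p * m / wbar
}

#' Introduce a novel mutant allele at low frequency
#'
#' Existing frequencies are scaled by \eqn{1 - p_0} and the mutant is appended
#' at frequency \eqn{p_0}, so the total stays exactly 1.  The canonical
#' initial frequency is \eqn{5 \times 10^{-5}} in infinite populations and
#' \eqn{1/(2N)} in finite ones.
#'
#' @param p numeric vector of allele frequencies.
#' @param p0 initial mutant frequency, in (0, 1).
#' @return Frequency vector of length `length(p) + 1`.
#' @examples
#' introduce_mutant(1, 5e-5)
#' @export
introduce_mutant <- function(p, p0) {
  if (length(p0) != 1 || is.na(p0) || p0 <= 0 || p0 >= 1)
    stop("'p0' must lie strictly between 0 and 1")
  c(p * (1 - p0), p0)
}

#' Will a rare mutant invade?
#'
#' In an infinite population a rare mutant increases in frequency exactly when
#' its marginal fitness exceeds the population mean fitness,
#' \eqn{m_{k} > \bar w}: one selection step multiplies its frequency by
#' \eqn{m_k / \bar w}.
#'
#' @inheritParams marginal_fitness
#' @param k index of the (rare) mutant allele; defaults to the last allele.
#' @return `TRUE` if the mutant's marginal fitness exceeds the mean fitness.
#' @examples
#' p <- introduce_mutant(1, 5e-5)
#' can_invade(p, matrix(c(0.5, 0.9, 0.9, 0.2), 2))
#' @export
can_invade <- function(p, W, k = length(p)) {
  m <- marginal_fitness(p, W)
  if (length(k) != 1 || is.na(k) || k < 1 || k > length(p))
    stop("mutant index 'k' out of range")
  m[k] > sum(p * m)
}

#' Wright-Fisher multinomial drift
#'
#' Resamples the next generation's allele frequencies as one multinomial draw
#' of \eqn{2N} gene copies with the current frequencies as probabilities.
#' Output frequencies are integer multiples of \eqn{1/(2N)}.
#'
#' @param p numeric vector of allele frequencies.
#' @param N diploid population size.
#' @return Frequency vector after drift.
#' @examples
#' set.seed(1)
#' drift_sample(c(0.6, 0.4), 1e4)
#' @export
drift_sample <- function(p, N) {
  if (length(N) != 1 || is.na(N) || N < 1)
    stop("'N' must be a positive population size")
  drop(rmultinom(1, 2 * N, p)) / (2 * N)
}

#' Remove extinct alleles and renormalize
#'
#' In infinite-population mode an allele is extinct when its frequency falls
#' strictly below the threshold (canonically \eqn{5 \times 10^{-5}}, the
#' mutant's initial frequency, so a mutant whose marginal fitness matches the
#' mean fitness survives its first generation).  In finite mode extinction is
#' an exact zero after drift.  Surviving frequencies are renormalized to sum
#' to 1 and the viability matrix (with any primary effects) is subset
#' accordingly.
#'
#' @param p numeric vector of allele frequencies.
#' @param W a [viability_matrix()].
#' @param threshold extinction cut for infinite mode.
#' @param finite logical; if `TRUE`, remove exact zeros only.
#' @return A list with elements `p` (renormalized survivor frequencies), `W`
#'   (subset viability matrix) and `keep` (logical vector of survivors).
#' @examples
#' W <- viability_matrix(matrix(c(0.5, 0.8, 0.8, 0.9), 2))
#' prune_extinct(c(0.99996, 4e-5), W)
#' @export
prune_extinct <- function(p, W, threshold = 5e-5, finite = FALSE) {
  stopifnot(inherits(W, "viability_matrix"))
  .check_dims(p, W$w)
  keep <- if (finite) p > 0 else p >= threshold
  if (!any(keep))
    stop("impossible state: all alleles would be extinct")
  p2 <- p[keep]
  p2 <- p2 / sum(p2)
  W$w <- W$w[keep, keep, drop = FALSE]
  if (!is.null(W$X)) W$X <- W$X[keep]
  list(p = p2, W = W, keep = keep)
}
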