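#' Interior equilibrium of an n-allele viability set
#'
#' At an interior equilibrium of the viability-selection recursion all
#' marginal fitnesses equal the mean fitness, so the equilibrium frequencies
#' solve \eqn{W p^* \propto 1}: \eqn{p^* = W^{-1} 1 / (1^T W^{-1} 1)}.  The
#' equilibrium is *feasible* when all components are strictly positive, and a
#' feasible interior equilibrium is asymptotically stable if and only if the
#' viability matrix has exactly one positive eigenvalue (equivalently,
#' \eqn{p^*} is the global maximizer of the mean fitness \eqn{p^T W p} on the
#' simplex).
#'
#' @param W a [viability_matrix()] or a plain symmetric matrix.
#' @param degenerate_tol eigenvalues of magnitude below this are treated as a
#'   numerical degeneracy.
#' @return An object of class `"equilibrium_result"`: a list with elements
#'   `p_star` (summing to 1, possibly with negative entries when infeasible),
#'   `feasible`, `stable` (the one-positive-eigenvalue condition; it certifies
#'   attraction only together with feasibility), `eigenvalues` and
#'   `degenerate`.
#' @examples
#' interior_equilibrium(matrix(c(0.5, 1, 1, 0.5), 2)) # overdominant: stable
#' interior_equilibrium(matrix(c(1, 0.5, 0.5, 1), 2)) # underdominant: not
#' @export
interior_equilibrium <- function(W, degenerate_tol = 1e-10) {
  w <- .wmat(W)
  if (nrow(w) != ncol(w) || !isSymmetric(w, tol = 1e-12))
    stop("'W' must be a symmetric square matrix")
  n <- nrow(w)
  ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
  degenerate <- any(abs(ev) < degenerate_tol)
  if (degenerate)
    stop("singular or near-singular viability matrix")
  q <- solve(w, rep(1, n))
  p_star <- q / sum(q)
  feasible <- all(p_star > 0)
  structure(
    list(p_star = p_star, feasible = feasible,
         stable = sum(ev > 0) == 1L, eigenvalues = ev,
         degenerate = degenerate),
    class = "equilibrium_result"
  )
}

#' Iterate the selection recursion to (boundary or interior) convergence
#'
#' Repeatedly applies [selection_step()] from a starting point (default: the
#' simplex center), stopping when the largest per-step frequency change falls
#' below `tol` or after `max_iter` iterations.  Mean fitness is a Lyapunov
#' function of this map, so trajectories converge monotonically toward a
#' local maximum of \eqn{p^T W p}; used to cross-validate the spectral
#' stability criterion of [interior_equilibrium()].
#'
#' @param W a [viability_matrix()] or a plain symmetric matrix.
#' @param p starting frequency vector.
#' @param max_iter iteration cap.
#' @param tol convergence tolerance on the sup-norm frequency change.
#' @return A list with elements `p`, `iterations` and `converged`.
#' @examples
#' iterate_selection(matrix(c(0.5, 1, 1, 0.5), 2))$p
#' @export
iterate_selection <- function(W, p = NULL, max_iter = 1e5, tol = 1e-14) {
  w <- .wmat(W)
  n <- nrow(w)
  p <- p %||% rep(1 / n, n)
  for (it in seq_len(max_iter)) {
    m <- drop(w %*% p)
    wbar <- sum(p * m)
    if (!is.finite(wbar) || wbar <= 0)
      stop("degenerate population: mean fitness is zero")
    p2 <- p * m / wbar
    delta <- max(abs(p2 - p))
    p <- p2
    if (delta < tol)
      return(list(p = p, iterations = it, converged = TRUE))
  }
  list(p = p, iterations = max_iter, converged = FALSE)
}

#' Scan random viability sets for feasible, stable full polymorphism
#'
#' The classical parameter-space baseline: draw `num_sets` symmetric n x n
#' viability matrices with i.i.d. U\[0, 1\] entries on and above the diagonal,
#' and count how many possess a feasible *and* stable interior equilibrium,
#' i.e. would maintain all n alleles indefinitely.  For n = 2 the proportion
#' is exactly the probability that the heterozygote viability is the largest
#' of three i.i.d. uniforms, 1/3; it collapses rapidly with n (a handful per
#' \eqn{10^5} sets at n = 5, essentially none at n = 6).  Near-singular draws
#' (an eigenvalue of magnitude < `degenerate_tol`) are discarded and redrawn.
#'
#' @param n allele count (>= 2).
#' @param num_sets number of random sets to draw.
#' @param degenerate_tol passed to the degeneracy check.
#' @return An object of class `"set_scan"`: a list with elements `n`,
#'   `num_sets`, `count` (feasible-and-stable sets) and `proportion`.
#' @examples
#' set.seed(1)
#' random_set_scan(2, 1000)
#' @export
random_set_scan <- function(n, num_sets, degenerate_tol = 1e-10) {
  n <- as.integer(n)
  if (is.na(n) || n < 2)
    stop("'n' must be an integer >= 2")
  num_sets <- as.integer(num_sets)
  if (is.na(num_sets) || num_sets < 1)
    stop("'num_sets' must be a positive integer")
  count <- 0L
  ones <- rep(1, n)
  ut <- upper.tri(matrix(0, n, n), diag = TRUE)
  lt <- lower.tri(matrix(0, n, n))
  ndraw <- n * (n + 1) / 2
  for (s in seq_len(num_sets)) {
    repeat {
      w <- matrix(0, n, n)
      w[ut] <- runif(ndraw)
      w[lt] <- t(w)[lt]
      ev <- eigen(w, symmetric = TRUE, only.values = TRUE)$values
      if (all(abs(ev) >= degenerate_tol)) break
    }
    if (sum(ev > 0) == 1L) {
      q <- solve(w, ones)
      if (all(q / sum(q) > 0)) count <- count + 1L
    }
  }
  structure(list(n = n, num_sets = num_sets, count = count,
                 proportion = count / num_sets),
            class = "set_scan")
}
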