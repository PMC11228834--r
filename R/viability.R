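#' Viability matrix of a multiallelic locus
#'
#' Container for the symmetric matrix of phenogenotype viabilities
#' \eqn{w_{ij}} of the currently extant alleles.  Two fitness-generation
#' methods are supported.  In the *uniform* method every viability involving a
#' new mutant is an independent draw from U\[0, 1\].  In the *generalized
#' dominance* method each allele carries a primary effect \eqn{X_i} and
#' \deqn{w_{ij} = \alpha (X_i + X_j) + (1 - 2\alpha) Y_{ij},}
#' with pairwise interaction effects \eqn{Y_{ij}} drawn uniformly at mutant
#' creation (and folded into \eqn{w}, never stored).  The weight
#' \eqn{\alpha \in [0, 1/2)} controls how strongly genotypes sharing an allele
#' resemble each other; \eqn{\alpha = 0} recovers the uniform method.
#'
#' @param w numeric square matrix of viabilities, symmetric, entries in
#'   \[0, 1\].
#' @param X optional numeric vector of per-allele primary effects (one per
#'   allele, entries in \[0, 1\]).  Supplying `X` switches the matrix to
#'   generalized-dominance mode.
#' @param alpha weight constant \eqn{\alpha \in [0, 1/2)}; only used in
#'   generalized-dominance mode.  Defaults to 1/3.
#' @return An object of class `"viability_matrix"`: a list with elements `w`,
#'   `X` (or `NULL`), `alpha` (or `NULL`) and `method` (`"uniform"` or
#'   `"gendom"`).
#' @seealso [add_mutant()], [apply_decay()], [init_viability()]
#' @examples
#' viability_matrix(matrix(0.5, 1, 1))
#' viability_matrix(diag(2) * 0.3 + 0.2, X = c(0.4, 0.9), alpha = 1/3)
#' @export
viability_matrix <- function(w, X = NULL, alpha = NULL) {
  w <- unname(as.matrix(w))
  if (nrow(w) != ncol(w))
    stop("'w' must be a square matrix")
  if (!isSymmetric(w, tol = 1e-12))
    stop("'w' must be symmetric: w_ij = w_ji")
  if (anyNA(w) || any(w < 0) || any(w > 1))
    stop("all viabilities must lie in [0, 1]")
  gendom <- !is.null(X)
  if (gendom) {
    alpha <- alpha %||% (1 / 3)
    if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha >= 0.5)
      stop("'alpha' must lie in [0, 1/2)")
    X <- as.numeric(X)
    if (length(X) != nrow(w))
      stop("'X' must supply one primary effect per allele")
    if (anyNA(X) || any(X < 0) || any(X > 1))
      stop("primary effects 'X' must lie in [0, 1]")
  } else if (!is.null(alpha)) {
    stop("'alpha' is only meaningful together with primary effects 'X'")
  }
  structure(
    list(w = w, X = if (gendom) X, alpha = if (gendom) alpha,
         method = if (gendom) "gendom" else "uniform"),
    class = "viability_matrix"
  )
}

#' Number of alleles tracked by a viability matrix
#'
#' @param W a [viability_matrix()].
#' @return Integer allele count.
#' @export
n_alleles <- function(W) {
  stopifnot(inherits(W, "viability_matrix"))
  nrow(W$w)
}

#' Initial single-allele viability matrix
#'
#' The canonical starting point of a simulation: one allele, \eqn{n = 1}.
#' Under the uniform method the single homozygote viability is fixed at
#' \eqn{w_{11} = 0.5}.  Under generalized dominance it is constructed from
#' fresh uniform draws, \eqn{w_{11} = 2\alpha X_1 + (1 - 2\alpha) Y_{11}}
#' (consuming two draws from the current RNG stream, \eqn{X_1} first).
#'
#' @param method `"uniform"` or `"gendom"`.
#' @param alpha weight constant for generalized dominance.
#' @return A single-allele [viability_matrix()].
#' @export
init_viability <- function(method = c("uniform", "gendom"), alpha = 1 / 3) {
  method <- match.arg(method)
  if (method == "uniform") {
    viability_matrix(matrix(0.5, 1, 1))
  } else {
    X1 <- runif(1)
    Y11 <- runif(1)
    viability_matrix(matrix(2 * alpha * X1 + (1 - 2 * alpha) * Y11, 1, 1),
                     X = X1, alpha = alpha)
  }
}

#' Append a novel mutant allele with freshly generated viabilities
#'
#' Extends an n-allele viability matrix to n + 1 alleles, generating the n + 1
#' new viabilities by the matrix's own method.  Uniform mode draws each
#' \eqn{w_{i,n+1}} independently from U\[0, 1\] (draw order
#' \eqn{i = 1, \dots, n + 1}).  Generalized-dominance mode first draws the
#' mutant's primary effect \eqn{X_{n+1}}, then interaction effects
#' \eqn{Y_{i,n+1}} for \eqn{i = 1, \dots, n + 1}, and sets
#' \eqn{w_{i,n+1} = \alpha (X_i + X_{n+1}) + (1 - 2\alpha) Y_{i,n+1}} using the
#' *current* (possibly decayed) primary effects \eqn{X_i}.  Existing entries
#' are untouched and symmetry is preserved.
#'
#' @param W a [viability_matrix()] with \eqn{n \ge 1} alleles.
#' @return A [viability_matrix()] with one more allele.
#' @examples
#' set.seed(1)
#' add_mutant(viability_matrix(matrix(0.5, 1, 1)))
#' @export
add_mutant <- function(W) {
  stopifnot(inherits(W, "viability_matrix"))
  n <- nrow(W$w)
  w2 <- matrix(0, n + 1, n + 1)
  w2[seq_len(n), seq_len(n)] <- W$w
  if (W$method == "uniform") {
    u <- runif(n + 1)
    w2[, n + 1] <- u
    w2[n + 1, ] <- u
    W$w <- w2
  } else {
    a <- W$alpha
    Xnew <- runif(1)
    Y <- runif(n + 1)
    col <- a * (c(W$X, Xnew) + Xnew) + (1 - 2 * a) * Y
    w2[, n + 1] <- col
    w2[n + 1, ] <- col
    W$w <- w2
    W$X <- c(W$X, Xnew)
  }
  W
}

#' Correlation between viabilities of genotypes sharing an allele
#'
#' Under generalized dominance, two genotypes \eqn{A_iA_j} and \eqn{A_iA_k}
#' share the primary effect \eqn{X_i}, which induces the closed-form
#' correlation
#' \deqn{\mathrm{Cor}(w_{ij}, w_{ik}) =
#'   \frac{\alpha^2}{1 - 4\alpha + 6\alpha^2}.}
#' At \eqn{\alpha = 1/3} the correlation is exactly 1/3; at \eqn{\alpha = 0}
#' viabilities are independent.
#'
#' @param alpha weight constant, in \[0, 1/2\] (1/2 admitted as a limit).
#' @return The correlation, a number in \[0, 1/2\].
#' @examples
#' gendom_correlation(1 / 3)
#' @export
gendom_correlation <- function(alpha) {
  if (length(alpha) != 1 || is.na(alpha) || alpha < 0 || alpha > 0.5)
    stop("'alpha' must lie in [0, 1/2]")
  alpha^2 / (1 - 4 * alpha + 6 * alpha^2)
}

#' Environmental decay model
#'
#' Describes how extant viabilities deteriorate each generation.  `"none"`
#' leaves fitnesses constant.  `"constant"` multiplies every viability by a
#' fixed factor \eqn{d \le 1} each generation (and, under generalized
#' dominance, every primary effect \eqn{X_i} likewise).  `"stochastic"` draws
#' an independent factor \eqn{d_{ij} \sim N(\mu, \sigma^2)} for each distinct
#' genotype pair each generation; the reference configuration
#' \eqn{N(0.999, 0.001^2)} places 15.87\% of its mass above 1, so most
#' genotypes decay slightly while some transiently improve.
#'
#' @param kind one of `"none"`, `"constant"`, `"stochastic"`.
#' @param d constant decay factor, \eqn{0 < d \le 1} (d = 1 means no decay).
#' @param mu,sigma mean and standard deviation of the per-genotype decay
#'   factor (stochastic kind; `sigma > 0`).
#' @return An object of class `"decay_model"`.
#' @examples
#' decay_model("constant", d = 0.9999)
#' decay_model("stochastic", mu = 0.999, sigma = 0.001)
#' @export
decay_model <- function(kind = c("none", "constant", "stochastic"),
                        d = 1, mu = 0.999, sigma = 0.001) {
  kind <- match.arg(kind)
  if (kind == "constant") {
    if (length(d) != 1 || is.na(d) || d <= 0 || d > 1)
      stop("constant decay requires 0 < d <= 1")
  }
  if (kind == "stochastic") {
    if (length(sigma) != 1 || is.na(sigma) || sigma <= 0)
      stop("stochastic decay requires sigma > 0")
    if (length(mu) != 1 || is.na(mu))
      stop("stochastic decay requires a finite mean 'mu'")
  }
  structure(
    list(kind = kind,
         d = if (kind == "constant") d,
         mu = if (kind == "stochastic") mu,
         sigma = if (kind == "stochastic") sigma),
    class = "decay_model"
  )
}

#' Apply one generation of environmental decay to a viability matrix
#'
#' Constant decay multiplies all viabilities (and primary effects, when
#' present) by `d`.  Stochastic decay draws one factor
#' \eqn{d_{ij} \sim N(\mu, \sigma^2)} per distinct genotype pair (upper
#' triangle in column-major order, diagonal included) and clamps the decayed
#' viabilities into \[0, 1\]; primary effects are left unchanged, as the decay
#' factors attach to genotypes, not alleles.  Symmetry is preserved.
#'
#' @param W a [viability_matrix()].
#' @param model a [decay_model()].
#' @return The decayed [viability_matrix()].
#' @examples
#' W <- viability_matrix(matrix(0.8, 1, 1))
#' apply_decay(W, decay_model("constant", d = 0.995))
#' @export
apply_decay <- function(W, model) {
  stopifnot(inherits(W, "viability_matrix"), inherits(model, "decay_model"))
  switch(model$kind,
    none = W,
    constant = {
      W$w <- model$d * W$w
      if (!is.null(W$X)) W$X <- model$d * W$X
      W
    },
    stochastic = {
      n <- nrow(W$w)
      ut <- upper.tri(W$w, diag = TRUE)
      dij <- rnorm(n * (n + 1) / 2, model$mu, model$sigma)
      w <- W$w
      w[ut] <- pmin(pmax(w[ut] * dij, 0), 1)
      lt <- lower.tri(w)
      w[lt] <- t(w)[lt]
      W$w <- w
      W
    }
  )
}
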