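# shared generators for property-style tests

random_sym_matrix <- function(n) {
  w <- matrix(0, n, n)
  w[upper.tri(w, diag = TRUE)] <- runif(n * (n + 1) / 2)
  w[lower.tri(w)] <- t(w)[lower.tri(w)]
  w
}

random_freq <- function(n) {
  p <- runif(n)
  p / sum(p)
}

# direct two-pass Pearson correlation, independent of stats::cor
pearson_two_pass <- function(x, y) {
  mx <- mean(x)
  my <- mean(y)
  sum((x - mx) * (y - my)) /
    sqrt(sum((x - mx)^2) * sum((y - my)^2))
}
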