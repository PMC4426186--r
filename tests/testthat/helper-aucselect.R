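# Shared fixtures and independent oracles. Everything here is deliberately
# naive/brute-force so that it cannot share a bug with the implementation.

# the 4-subject toy set used for hand-computed values:
# controls {1, 3}, cases {2, 4}
toy_data <- function() {
  biomarker_data(matrix(c(1, 3, 2, 4), ncol = 1), c(0L, 0L, 1L, 1L), "m")
}

# brute-force AUC: normalized Mann-Whitney kernel over all n0 * n1 pairs
auc_brute <- function(x0, x1) {
  k <- outer(x0, x1, function(a, b) (a < b) + 0.5 * (a == b))
  mean(k)
}

# placement of value v against opposite-group values y:
# proportion strictly below plus half of the ties
placement_brute <- function(v, y) {
  mean((y < v) + 0.5 * (y == v))
}

# random small dataset with ties (integer-valued marker columns)
random_tied_data <- function(d = 2, n0 = NULL, n1 = NULL, levels = 6) {
  n0 <- n0 %||% sample(3:9, 1)
  n1 <- n1 %||% sample(3:9, 1)
  X <- matrix(sample.int(levels, (n0 + n1) * d, replace = TRUE), n0 + n1, d)
  biomarker_data(X, rep(c(0L, 1L), c(n0, n1)))
}

# continuous two-group gaussian data, d markers with common correlation
random_normal_data <- function(n0, n1, d = 2, rho = 0.5, delta = 1) {
  S <- matrix(rho, d, d)
  diag(S) <- 1
  X <- matrix(rnorm((n0 + n1) * d), n0 + n1) %*% chol(S)
  X[(n0 + 1):(n0 + n1), ] <- X[(n0 + 1):(n0 + n1), ] + delta
  biomarker_data(X, rep(c(0L, 1L), c(n0, n1)))
}

# Monte-Carlo tolerance used across the simulation-based checks:
# three binomial standard errors plus a 0.3 percentage-point allowance for
# the reduced number of bootstrap draws
mc_tol <- function(p, nsim) 3 * sqrt(p * (1 - p) / nsim) + 0.003
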