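## Wild Bootstrap approximation of the joint null distribution of the max
## statistic, and the conventional casewise bootstrap shipped for
## comparison.

#' Wild Bootstrap weights
#'
#' Draws i.i.d. random weights with mean 0 and variance 1 from one of the
#' three supported laws: Rademacher (random signs), standard normal, or
#' uniform on `[-sqrt(12)/2, sqrt(12)/2]`.
#'
#' @param n number of weights.
#' @param scheme `"normal"`, `"rademacher"` or `"uniform"`.
#' @param seed optional integer; when given, the weights are drawn from a
#'   private stream and the caller's RNG state is preserved.
#' @return numeric vector of length `n`.
#' @export
wb_weights <- function(n, scheme = c("normal", "rademacher", "uniform"),
                       seed = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(n >= 1)
  draw <- function() {
    switch(scheme,
      normal = stats::rnorm(n),
      rademacher = sample(c(-1, 1), n, replace = TRUE),
      uniform = stats::runif(n, -sqrt(3), sqrt(3))
    )
  }
  if (is.null(seed)) draw() else with_preserved_rng(draw(), seed = seed)
}

# weight matrix for nboot draws: one column per draw, rows in subject order
# (controls first, then cases), filled from consecutive stream values
.wb_weight_matrix <- function(N, nboot, scheme) {
  switch(scheme,
    normal = matrix(stats::rnorm(N * nboot), N, nboot),
    rademacher = matrix(sample(c(-1, 1), N * nboot, replace = TRUE), N, nboot),
    uniform = matrix(stats::runif(N * nboot, -sqrt(3), sqrt(3)), N, nboot)
  )
}

# bootstrap statistics for a block of draws, fully vectorized:
# Z*_is = W_is (Z_is - Zbar_i); groupwise means and variances of the Z* are
# linear resp. quadratic in W, so each is one matrix product.
# Returns a d x nboot matrix of studentized statistics.
.wb_stat_matrix <- function(fit, W0, W1, denominator = "paired") {
  n0 <- nrow(fit$Z0c)
  n1 <- nrow(fit$Z1c)
  M0 <- crossprod(fit$Z0c, W0) / n0
  M1 <- crossprod(fit$Z1c, W1) / n1
  S0 <- (crossprod(fit$Z0c^2, W0^2) - n0 * M0^2) / (n0 - 1)
  S1 <- (crossprod(fit$Z1c^2, W1^2) - n1 * M1^2) / (n1 - 1)
  # "paired" matches the pairing used in the covariance estimator
  # V-hat = N (V0/n0 + V1/n1), which is what gives T* unit conditional
  # variance; "crossed" swaps the group indices (equivalent when n0 = n1)
  den <- if (denominator == "paired") S0 / n0 + S1 / n1 else S1 / n0 + S0 / n1
  (M1 - M0) / sqrt(den)
}

# max statistics A*_j over nboot draws; draws yielding a non-finite
# statistic in any marker (zero bootstrap variance) are rejected and
# redrawn, with a hard cap
.wb_max_stats <- function(fit, nboot, scheme = "normal",
                          denominator = "paired", max_redraw = 100L) {
  N <- nrow(fit$Z0c) + nrow(fit$Z1c)
  n0 <- nrow(fit$Z0c)
  W <- .wb_weight_matrix(N, nboot, scheme)
  Tst <- .wb_stat_matrix(
    fit, W[seq_len(n0), , drop = FALSE],
    W[(n0 + 1):N, , drop = FALSE], denominator
  )
  A <- apply(Tst, 2L, max)
  bad <- which(!is.finite(A))
  tries <- 0L
  while (length(bad)) {
    tries <- tries + 1L
    if (tries > max_redraw) {
      stop("wild bootstrap: degenerate draws persisted after ", max_redraw,
        " redraw rounds (constant placements?)",
        call. = FALSE
      )
    }
    W <- .wb_weight_matrix(N, length(bad), scheme)
    Tst <- .wb_stat_matrix(
      fit, W[seq_len(n0), , drop = FALSE],
      W[(n0 + 1):N, , drop = FALSE], denominator
    )
    A[bad] <- apply(Tst, 2L, max)
    bad <- bad[!is.finite(A[bad])]
  }
  A
}

# conventional (casewise, Efron-type) bootstrap of the studentized logit
# max statistic, centered at the original estimates; comparison only
.efron_max_stats <- function(X, i0, i1, auc_hat, nboot, max_redraw = 100L) {
  N <- length(i0) + length(i1)
  g0 <- stats::qlogis(auc_hat)
  A <- numeric(nboot)
  for (j in seq_len(nboot)) {
    ok <- FALSE
    for (k in seq_len(max_redraw)) {
      b0 <- sample(i0, replace = TRUE)
      b1 <- sample(i1, replace = TRUE)
      Xb <- X[c(b0, b1), , drop = FALSE]
      tb <- .rank_tables(Xb, seq_along(i0), length(i0) + seq_along(i1))
      fb <- .core_fit(tb)
      if (any(fb$auc <= 0 | fb$auc >= 1)) next
      vb <- diag(fb$V)
      sb <- vb / (fb$auc * (1 - fb$auc))^2
      A[j] <- max((stats::qlogis(fb$auc) - g0) * sqrt(N / sb))
      ok <- TRUE
      break
    }
    if (!ok) {
      stop("casewise bootstrap: degenerate resamples persisted after ",
        max_redraw, " redraws",
        call. = FALSE
      )
    }
  }
  A
}
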