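## Scenario generators and the Monte-Carlo engine for familywise type-I
## error and power studies.

#' Correlation matrix for the "unstructured" covariance setting
#'
#' A fixed, reproducible random correlation matrix with spread eigenvalues:
#' a seeded standard-normal matrix is orthogonalized by QR, the eigenvalues
#' are set to `seq(0.2, 2, length.out = d)`, and the resulting matrix is
#' rescaled to unit diagonal. The construction depends only on `d`, so the
#' "unstructured" scenario is identical across machines and runs.
#'
#' @param d dimension.
#' @param seed the construction seed; the default is the shipped constant.
#' @return a `d x d` correlation matrix.
#' @export
unstructured_correlation <- function(d, seed = 20150501L) {
  if (d == 1L) {
    return(diag(1))
  }
  with_preserved_rng(
    {
      Q <- qr.Q(qr(matrix(stats::rnorm(d * d), d, d)))
      lam <- seq(0.2, 2, length.out = d)
      stats::cov2cor(Q %*% (lam * t(Q)))
    },
    seed = seed
  )
}

#' Group covariance matrix for a simulation scenario
#'
#' * `compound_symmetry`: unit variances, common off-diagonal correlation
#'   `rho` (positive semidefinite for any `rho` in `[0, 1)`).
#' * `unstructured`: the fixed seeded correlation of
#'   [unstructured_correlation()] (ignores `rho`).
#' * `hetero_diagonal_positive_pairing` / `hetero_diagonal_negative_pairing`:
#'   diagonal covariance with marker variances increasing across markers
#'   (`seq(1, 2, length.out = d)`); under positive pairing the *larger*
#'   group receives these variances scaled by 2 and the smaller group the
#'   unscaled set; negative pairing swaps the assignment.
#'
#' @param structure one of the four structure names.
#' @param rho common correlation for compound symmetry, in `[0, 1)`.
#' @param d number of markers.
#' @param group `"larger"` or `"smaller"` — which group's covariance to
#'   build (only relevant for the heterogeneous structures).
#' @return a `d x d` covariance matrix.
#' @export
build_covariance <- function(structure = c(
                               "compound_symmetry", "unstructured",
                               "hetero_diagonal_positive_pairing",
                               "hetero_diagonal_negative_pairing"
                             ),
                             rho = 0.9, d, group = c("larger", "smaller")) {
  structure <- match.arg(structure)
  group <- match.arg(group)
  stopifnot(d >= 1)
  if (structure == "compound_symmetry") {
    if (rho < 0 || rho >= 1) stop("rho must lie in [0, 1)", call. = FALSE)
    S <- matrix(rho, d, d)
    diag(S) <- 1
    return(S)
  }
  if (structure == "unstructured") {
    return(unstructured_correlation(d))
  }
  base <- if (d == 1L) 1 else seq(1, 2, length.out = d)
  scaled <- 2 * base
  pos <- structure == "hetero_diagonal_positive_pairing"
  v <- if ((group == "larger") == pos) scaled else base
  diag(v, d, d)
}

# discretised AUC of two normals cut at shared thresholds into 5 categories
.ordinal_auc <- function(delta, thr, sd0 = 1, sd1 = 1) {
  p0 <- diff(c(0, stats::pnorm(thr / sd0), 1))
  p1 <- diff(c(0, stats::pnorm((thr - delta) / sd1), 1))
  F0lo <- cumsum(c(0, p0))[seq_along(p0)]
  sum(p1 * (F0lo + p0 / 2))
}

# location shift putting the (possibly discretised) AUC at `target`
.calibrate_shift <- function(target, family, sd0, sd1,
                             thr = c(-1.5, -0.5, 0.5, 1.5)) {
  if (family != "ordinal5") {
    # exact binormal identity: AUC = Phi(delta / sqrt(sd0^2 + sd1^2));
    # the log-normal inherits it by monotone invariance of the AUC
    return(stats::qnorm(target) * sqrt(sd0^2 + sd1^2))
  }
  if (target == 0.5) {
    return(0)
  }
  upper <- .ordinal_auc(20 * max(sd0, sd1, 1), thr, sd0, sd1)
  if (target > upper || target < 1 - upper) {
    stop("target AUC ", target, " unreachable after 5-point discretisation ",
      "(attainable range ", format(1 - upper, digits = 4), " to ",
      format(upper, digits = 4), ")",
      call. = FALSE
    )
  }
  lo <- if (target > 0.5) 0 else -20 * max(sd0, sd1, 1)
  hi <- if (target > 0.5) 20 * max(sd0, sd1, 1) else 0
  stats::uniroot(
    function(dl) .ordinal_auc(dl, thr, sd0, sd1) - target,
    c(lo, hi),
    tol = 1e-6
  )$root
}

#' Describe one Monte-Carlo simulation cell
#'
#' Captures the full data-generating configuration of one cell of the
#' simulation study plus the inference methods to evaluate on it. Defaults
#' are the standard scenario of the study: multivariate normal markers with
#' compound-symmetric correlation `rho = 0.9`, `d = 5` tests, total sample
#' size `N = 100` with a 1:1 case-control ratio, one-sided
#' `alpha = 0.025`.
#'
#' @param family `"normal"`, `"lognormal"` (elementwise exponential of the
#'   normal draws — identical midranks, so a pure robustness check of the
#'   rank methods), or `"ordinal5"` (latent normal cut at the shared
#'   thresholds `-1.5, -0.5, 0.5, 1.5` into a 5-point grading scale, with
#'   the case shift calibrated so the *discretised* AUC hits `true_auc`).
#' @param cov_structure see [build_covariance()].
#' @param rho compound-symmetry correlation.
#' @param d number of markers.
#' @param N total number of subjects.
#' @param ccr case:control ratio 1:`ccr`; cases are the smaller group:
#'   `n1 = round(N / (ccr + 1))`, `n0 = N - n1`.
#' @param true_auc scalar or `d`-vector of true AUCs.
#' @param auc0 threshold tested against. The least favorable null
#'   configuration has `true_auc == auc0`.
#' @param methods character vector of methods (see [auc_select()]) all
#'   evaluated on the same simulated datasets.
#' @param weights,nboot Wild Bootstrap settings.
#' @param nsim Monte-Carlo replications.
#' @param alpha one-sided level.
#' @param seed master seed; replication `r` uses the derived child seed
#'   `(seed * 1000003 + r * 7919) mod (2^31 - 1)`, so individual
#'   replications are reproducible independently of `nsim`.
#' @param id optional scenario identifier used in result tables.
#' @return an object of class `sim_scenario`.
#' @export
sim_scenario <- function(family = "normal", cov_structure = "compound_symmetry",
                         rho = 0.9, d = 5L, N = 100L, ccr = 1, true_auc = 0.5,
                         auc0 = 0.5, methods = "wb", weights = "normal",
                         nboot = 1000L, nsim = 1000L, alpha = 0.025, seed = 1L,
                         id = NULL) {
  family <- match.arg(family, c("normal", "lognormal", "ordinal5"))
  cov_structure <- match.arg(cov_structure, c(
    "compound_symmetry", "unstructured",
    "hetero_diagonal_positive_pairing", "hetero_diagonal_negative_pairing"
  ))
  methods <- vapply(
    methods,
    function(m) match.arg(m, c("wb", "logit", "mcp", "bonferroni", "unadjusted", "efron")),
    character(1),
    USE.NAMES = FALSE
  )
  weights <- match.arg(weights, c("normal", "rademacher", "uniform"))
  d <- as.integer(d)
  N <- as.integer(N)
  true_auc <- rep_len(as.numeric(true_auc), d)
  stopifnot(
    d >= 1, N >= 8, ccr >= 1, all(true_auc > 0), all(true_auc < 1),
    auc0 > 0, auc0 < 1, alpha > 0, alpha < 0.5, nsim >= 1, nboot >= 1
  )
  n1 <- as.integer(round(N / (ccr + 1)))
  n0 <- N - n1
  if (is.null(id)) {
    id <- paste(family, cov_structure, paste0("rho", rho), paste0("d", d),
      paste0("N", N), paste0("ccr1to", ccr),
      paste0("auc", paste(unique(round(true_auc, 4)), collapse = "_")),
      paste0("auc0_", auc0), paste0("seed", seed),
      sep = "-"
    )
  }
  structure(
    list(
      family = family, cov_structure = cov_structure, rho = rho, d = d,
      N = N, ccr = ccr, n0 = n0, n1 = n1, true_auc = true_auc, auc0 = auc0,
      methods = methods, weights = weights, nboot = as.integer(nboot),
      nsim = as.integer(nsim), alpha = alpha, seed = as.integer(seed), id = id
    ),
    class = "sim_scenario"
  )
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat("<sim_scenario> ", x$id, "\n", sep = "")
  cat(
    "  ", x$family, ", ", x$cov_structure, " (rho ", x$rho, "), d = ", x$d,
    ", N = ", x$N, " (", x$n0, "/", x$n1, "), true AUC ",
    paste(unique(x$true_auc), collapse = "/"), " vs AUC0 ", x$auc0, "\n",
    sep = ""
  )
  cat(
    "  methods: ", paste(x$methods, collapse = ", "), "; nsim ", x$nsim,
    ", nboot ", x$nboot, ", alpha ", x$alpha, ", seed ", x$seed, "\n",
    sep = ""
  )
  invisible(x)
}

# precompute everything per-replication generation needs
.scenario_prep <- function(sc) {
  hetero <- grepl("^hetero", sc$cov_structure)
  grp0 <- if (sc$n0 >= sc$n1) "larger" else "smaller"
  grp1 <- if (grp0 == "larger") "smaller" else "larger"
  S0 <- build_covariance(sc$cov_structure, sc$rho, sc$d, group = grp0)
  S1 <- if (hetero) build_covariance(sc$cov_structure, sc$rho, sc$d, group = grp1) else S0
  sd0 <- sqrt(diag(S0))
  sd1 <- sqrt(diag(S1))
  delta <- vapply(
    seq_len(sc$d),
    function(l) .calibrate_shift(sc$true_auc[l], sc$family, sd0[l], sd1[l]),
    numeric(1)
  )
  list(
    ch0 = chol(S0), ch1 = chol(S1), delta = delta,
    thr = c(-1.5, -0.5, 0.5, 1.5),
    status = rep(c(0L, 1L), c(sc$n0, sc$n1))
  )
}

.sim_matrix <- function(sc, prep) {
  X0 <- matrix(stats::rnorm(sc$n0 * sc$d), sc$n0) %*% prep$ch0
  X1 <- matrix(stats::rnorm(sc$n1 * sc$d), sc$n1) %*% prep$ch1
  X1 <- sweep(X1, 2L, prep$delta, `+`)
  X <- rbind(X0, X1)
  switch(sc$family,
    normal = X,
    lognormal = exp(X),
    ordinal5 = matrix(findInterval(X, prep$thr) + 1, nrow(X))
  )
}

#' Simulate one dataset from a scenario
#'
#' Controls are drawn from a centered `d`-variate normal with the scenario
#' covariance and cases from the same law shifted marker-wise by
#' `delta = qnorm(true_auc) * sqrt(sd0^2 + sd1^2)` (the binormal identity),
#' then transformed according to the distribution family.
#'
#' @param scenario a [sim_scenario()].
#' @param seed optional seed (drawn from the current stream when `NULL`).
#' @return a tibble with a `status` column (0 control / 1 case, controls
#'   first) and one column per marker.
#' @export
sim_dataset <- function(scenario, seed = NULL) {
  stopifnot(inherits(scenario, "sim_scenario"))
  prep <- .scenario_prep(scenario)
  X <- if (is.null(seed)) {
    .sim_matrix(scenario, prep)
  } else {
    with_preserved_rng(.sim_matrix(scenario, prep), seed = seed)
  }
  colnames(X) <- paste0("marker_", seq_len(scenario$d))
  dplyr::bind_cols(tibble::tibble(status = prep$status), tibble::as_tibble(X))
}

.child_seed <- function(seed, r) {
  (as.double(seed) * 1000003 + as.double(r) * 7919) %% 2147483647
}

#' Run a Monte-Carlo study cell
#'
#' Simulates `nsim` datasets from the scenario and applies every requested
#' method to each of them (shared datasets, i.e. common random numbers
#' across methods). The empirical rejection rate of the global null is the
#' familywise type-I error when `true_auc == auc0` (least favorable null)
#' and the global power otherwise. Replications that produce a degenerate
#' marker (estimated AUC 0 or 1) are repaired by the conservative boundary
#' replacement before testing, mirroring the recommended analysis path.
#'
#' @param scenario a [sim_scenario()].
#' @param progress emit a progress message every 100 replications.
#' @param quantile_prob_tol,quantile_maxpts accuracy of the equicoordinate
#'   quantile computed per replication for methods `"mcp"`/`"logit"`; the
#'   defaults bound the quantile error well below Monte-Carlo noise.
#' @return a tibble with one row per method: scenario descriptors, `method`,
#'   `estimand` (`"fwer"` or `"power"`), `rejection_rate`, `mc_se`
#'   (`sqrt(p(1-p)/nsim)`), and `marker_rates` (list column of per-marker
#'   rejection rates).
#' @export
run_study <- function(scenario, progress = FALSE,
                      quantile_prob_tol = 1e-5, quantile_maxpts = 2000L) {
  sc <- scenario
  stopifnot(inherits(sc, "sim_scenario"))
  prep <- .scenario_prep(sc)
  i0 <- seq_len(sc$n0)
  i1 <- sc$n0 + seq_len(sc$n1)
  nm <- length(sc$methods)
  rej <- matrix(FALSE, sc$nsim, nm, dimnames = list(NULL, sc$methods))
  mrej <- array(FALSE, c(sc$nsim, sc$d, nm))
  needs_q <- any(sc$methods %in% c("mcp", "logit"))

  with_preserved_rng({
    for (r in seq_len(sc$nsim)) {
      set.seed(.child_seed(sc$seed, r))
      X <- .sim_matrix(sc, prep)
      tb <- .rank_tables(X, i0, i1)
      fit <- .core_fit(tb)
      if (any(fit$auc <= 0 | fit$auc >= 1)) {
        X <- .boundary_fix_matrix(X, i0, i1, fit$auc)
        tb <- .rank_tables(X, i0, i1)
        fit <- .core_fit(tb)
      }
      v <- diag(fit$V)
      Tl <- .test_statistics(fit$auc, v, sc$auc0, sc$N)
      lg <- .logit_pieces(fit$auc, v, sc$auc0, sc$N)
      zR <- if (needs_q) {
        equicoordinate_quantile(stats::cov2cor(fit$V), sc$alpha,
          prob_tol = quantile_prob_tol, maxpts = quantile_maxpts
        )
      }
      for (m in seq_len(nm)) {
        sel <- switch(sc$methods[m],
          unadjusted = Tl >= stats::qnorm(1 - sc$alpha),
          bonferroni = Tl >= stats::qnorm(1 - sc$alpha / sc$d),
          mcp = Tl >= zR,
          logit = lg$stat >= zR,
          wb = {
            A <- .wb_max_stats(fit, sc$nboot, scheme = sc$weights)
            lg$stat >= sort(A)[ceiling((1 - sc$alpha) * sc$nboot)]
          },
          efron = {
            A <- .efron_max_stats(X, i0, i1, fit$auc, sc$nboot)
            lg$stat >= sort(A)[ceiling((1 - sc$alpha) * sc$nboot)]
          }
        )
        mrej[r, , m] <- sel
        rej[r, m] <- any(sel)
      }
      if (progress && r %% 100L == 0L) {
        message("[", sc$id, "] replication ", r, "/", sc$nsim)
      }
    }
  })

  p <- colMeans(rej)
  tibble::tibble(
    id = sc$id, family = sc$family, cov_structure = sc$cov_structure,
    rho = sc$rho, d = sc$d, N = sc$N, ccr = sc$ccr,
    true_auc = paste(round(sc$true_auc, 4), collapse = ","), auc0 = sc$auc0,
    method = sc$methods, weights = ifelse(sc$methods == "wb", sc$weights, NA),
    nboot = ifelse(sc$methods %in% c("wb", "efron"), sc$nboot, NA_integer_),
    nsim = sc$nsim, alpha = sc$alpha, seed = sc$seed,
    estimand = if (all(sc$true_auc == sc$auc0)) "fwer" else "power",
    rejection_rate = unname(p),
    mc_se = sqrt(unname(p) * (1 - unname(p)) / sc$nsim),
    marker_rates = lapply(seq_len(nm), function(m) {
      colMeans(matrix(mrej[, , m], nrow = sc$nsim))
    })
  )
}

#' Synthetic dataset shaped like the intestinal-current-measurement example
#'
#' Generates a synthetic stand-in for the motivating cystic-fibrosis
#' biomarker study (the original data are not public): 67 subjects — 26
#' cases and 41 controls — with four strongly correlated continuous markers
#' of good-to-excellent accuracy, the fourth constructed to separate cases
#' from controls perfectly (estimated AUC exactly 1) so that the
#' boundary-fix path can be exercised.
#'
#' @param seed integer seed; the same seed reproduces the fixture exactly.
#' @return a tibble with a `status` column (labels `"control"` / `"case"`)
#'   and markers `marker_1` ... `marker_4`.
#' @export
make_icm_like_fixture <- function(seed = 20150501L) {
  n0 <- 41L
  n1 <- 26L
  d <- 4L
  S <- matrix(0.8, d, d)
  diag(S) <- 1
  ch <- chol(S)
  target <- c(0.86, 0.80, 0.92, 0.98)
  delta <- stats::qnorm(target) * sqrt(2)
  X <- with_preserved_rng(
    {
      X0 <- matrix(stats::rnorm(n0 * d), n0) %*% ch
      X1 <- sweep(matrix(stats::rnorm(n1 * d), n1) %*% ch, 2L, delta, `+`)
      # force complete separation on marker 4
      gap <- max(X0[, 4]) - min(X1[, 4])
      if (gap >= 0) X1[, 4] <- X1[, 4] + gap + 0.5
      rbind(X0, X1)
    },
    seed = seed
  )
  colnames(X) <- paste0("marker_", 1:d)
  dplyr::bind_cols(
    tibble::tibble(status = rep(c("control", "case"), c(n0, n1))),
    tibble::as_tibble(round(X, 4))
  )
}
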