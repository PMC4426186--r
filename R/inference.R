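## Asymptotic simultaneous tests and one-sided confidence bounds for the
## AUC vector against a non-inferiority threshold auc0.

# evaluate `expr` under a temporary RNG state; the caller's stream is
# untouched (used to make quasi-Monte-Carlo rectangle probabilities and
# whole analyses reproducible without side effects)
with_preserved_rng <- function(expr, seed = NULL) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  if (!is.null(seed)) set.seed(seed)
  expr
}

# deterministic multivariate-normal rectangle probability P(all <= z);
# the quasi-Monte-Carlo routine is run under a fixed internal seed so the
# same (z, R) always yields the same probability
.mvn_rect_prob <- function(z, R, abseps = 1e-6, maxpts = 25000L) {
  if (nrow(R) == 1L) {
    return(stats::pnorm(z))
  }
  with_preserved_rng(
    as.numeric(mvtnorm::pmvnorm(
      lower = -Inf, upper = rep(z, nrow(R)), corr = R,
      algorithm = mvtnorm::GenzBretz(abseps = abseps, releps = 0, maxpts = maxpts)
    )),
    seed = 20150501L
  )
}

.check_correlation <- function(R) {
  if (!is.matrix(R) || nrow(R) != ncol(R)) {
    stop("correlation matrix must be square", call. = FALSE)
  }
  if (anyNA(R)) stop("correlation matrix contains NA", call. = FALSE)
  if (max(abs(R - t(R))) > 1e-8) {
    stop("correlation matrix is not symmetric", call. = FALSE)
  }
  if (max(abs(diag(R) - 1)) > 1e-8) {
    stop("correlation matrix must have unit diagonal", call. = FALSE)
  }
  if (max(abs(R)) > 1 + 1e-8) {
    stop("correlation entries must lie in [-1, 1]", call. = FALSE)
  }
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8) {
    stop("correlation matrix is not positive semidefinite", call. = FALSE)
  }
  invisible(R)
}

#' One-sided equicoordinate quantile of a multivariate normal
#'
#' The scalar `z` such that a centered multivariate normal vector with
#' correlation matrix `R` satisfies `P(all components <= z) = 1 - alpha`.
#' This is the critical value of the multiple contrast test: it lies between
#' the unadjusted normal quantile (attained in the comonotone limit, all
#' correlations 1) and the Bonferroni quantile `z_{1 - alpha/d}` (attained
#' under independence as `d` grows), which also provide the bracket for the
#' root search.
#'
#' Rectangle probabilities are computed by a quasi-Monte-Carlo routine run
#' under a fixed internal seed, so quantiles are reproducible across calls
#' and do not disturb the caller's RNG stream. Perfectly correlated
#' duplicate components are collapsed before integration (the singular
#' comonotone limit), so near-duplicate markers are handled; non-symmetric
#' or non-PSD inputs are an error.
#'
#' @param R correlation matrix.
#' @param alpha one-sided level, in (0, 0.5).
#' @param prob_tol absolute tolerance on the coverage probability.
#' @param maxpts maximum integration points per rectangle probability.
#' @return the quantile, a single number.
#' @examples
#' equicoordinate_quantile(diag(1), 0.025) # qnorm(0.975)
#' @export
equicoordinate_quantile <- function(R, alpha = 0.025, prob_tol = 1e-6,
                                    maxpts = 25000L) {
  if (is.null(dim(R))) R <- matrix(R, 1L, 1L)
  .check_correlation(R)
  stopifnot(alpha > 0, alpha < 0.5)
  d_full <- nrow(R)
  # collapse perfectly correlated (comonotone) duplicates
  keep <- rep(TRUE, d_full)
  if (d_full > 1L) {
    for (j in 2:d_full) {
      prev <- which(keep[seq_len(j - 1L)])
      if (any(abs(R[j, prev] - 1) < 1e-10)) keep[j] <- FALSE
    }
  }
  R <- R[keep, keep, drop = FALSE]
  d <- nrow(R)
  if (d == 1L) {
    return(stats::qnorm(1 - alpha))
  }
  lo <- stats::qnorm(1 - alpha) - 1e-3
  hi <- stats::qnorm(1 - alpha / d) + 1e-3
  f <- function(z) .mvn_rect_prob(z, R, abseps = prob_tol, maxpts = maxpts) - (1 - alpha)
  stats::uniroot(f, c(lo, hi), tol = prob_tol, extendInt = "upX")$root
}

# studentized statistics on the raw AUC scale, Wald-type with the
# hypothesized value substituted for the unknown true AUC
.test_statistics <- function(auc, v, auc0, N) {
  (auc - auc0) * sqrt(N / v)
}

# logit scale: delta-method variance s = v / (auc (1 - auc))^2
.logit_pieces <- function(auc, v, auc0, N) {
  s <- v / (auc * (1 - auc))^2
  list(s = s, stat = (stats::qlogis(auc) - stats::qlogis(auc0)) * sqrt(N / s))
}

#' Replace boundary measurements of a degenerate marker
#'
#' A marker whose estimated AUC equals 1 has zero estimated variance and an
#' infinite logit, so no interval can be computed. The remedy is the minimal
#' data modification of replacing the largest control measurement with the
#' smallest case measurement for that marker (mirrored for AUC = 0: the
#' smallest case measurement is replaced with the largest control
#' measurement). The modification is conservative: the estimated effect
#' decreases and its variance increases.
#'
#' @param data a `biomarker_data` object.
#' @param marker marker name or column index; default: every degenerate
#'   marker.
#' @return a modified copy of `data`. Applying the fix to a non-degenerate
#'   marker is a warning and a no-op.
#' @export
apply_boundary_fix <- function(data, marker = NULL) {
  stopifnot(inherits(data, "biomarker_data"))
  tab <- placement_tables(data)
  auc <- estimate_auc(tab)
  idx <- if (is.null(marker)) {
    which(auc <= 0 | auc >= 1)
  } else if (is.character(marker)) {
    match(marker, data$marker_names)
  } else {
    as.integer(marker)
  }
  if (anyNA(idx)) stop("unknown marker", call. = FALSE)
  X <- data$values
  i0 <- which(data$status == 0L)
  i1 <- which(data$status == 1L)
  for (l in idx) {
    if (auc[l] >= 1) {
      X[i0[which.max(X[i0, l])], l] <- min(X[i1, l])
    } else if (auc[l] <= 0) {
      X[i1[which.min(X[i1, l])], l] <- max(X[i0, l])
    } else {
      warning("marker `", data$marker_names[l],
        "` is not degenerate; data left unchanged",
        call. = FALSE
      )
    }
  }
  biomarker_data(X, data$status, data$marker_names)
}

# internal: matrix-level boundary fix used by the simulation engine
.boundary_fix_matrix <- function(X, i0, i1, auc) {
  for (l in which(auc >= 1)) {
    X[i0[which.max(X[i0, l])], l] <- min(X[i1, l])
  }
  for (l in which(auc <= 0)) {
    X[i1[which.min(X[i1, l])], l] <- max(X[i0, l])
  }
  X
}

# adjusted p-values: for the joint methods, p(l) = 1 - P(all components of
# N(0, R-hat) <= t(l)); compatible with the single-step decision rule
.mcp_p_values <- function(stats_vec, R, prob_tol = 1e-6, maxpts = 25000L) {
  vapply(
    stats_vec,
    function(t) 1 - .mvn_rect_prob(t, R, abseps = prob_tol, maxpts = maxpts),
    numeric(1)
  )
}

#' Simultaneous one-sided AUC inference and marker selection
#'
#' Tests, for each of `d` markers measured on the same subjects, the
#' non-inferiority null hypothesis `AUC <= auc0` against `AUC > auc0` with
#' strong familywise error control, and returns compatible one-sided
#' simultaneous lower confidence bounds. A marker is *selected* when its
#' lower bound exceeds `auc0` (equivalently, when its statistic reaches the
#' method's critical value).
#'
#' Methods:
#' \describe{
#'   \item{`"wb"`}{Wild Bootstrap (default): the joint null distribution of
#'     the max statistic is approximated by multiplying centered placements
#'     with i.i.d. mean-0 variance-1 random weights; the logit-scale
#'     statistics are compared with the empirical equicoordinate quantile of
#'     the bootstrap max statistics. Recommended for small samples and high
#'     accuracies.}
#'   \item{`"logit"`}{multiple contrast test on logit-transformed AUCs with
#'     the equicoordinate quantile of `N(0, R-hat)`.}
#'   \item{`"mcp"`}{multiple contrast test on the raw AUC scale.}
#'   \item{`"bonferroni"`, `"unadjusted"`}{classical per-marker Wald bounds
#'     with `z_{1-alpha/d}` resp. `z_{1-alpha}`.}
#'   \item{`"efron"`}{conventional casewise bootstrap of the logit max
#'     statistic; shipped only as a comparison procedure (it is known to be
#'     liberal at high AUCs) and not recommended for selection.}
#' }
#'
#' @param data data frame (one row per subject) or `biomarker_data` object.
#' @param status status column (bare name or string) when `data` is a data
#'   frame; ignored otherwise.
#' @param auc0 non-inferiority threshold for the AUC, in (0, 1).
#' @param alpha one-sided level; default 0.025 (one-sided 97.5% simultaneous
#'   confidence bounds, the conventional non-inferiority level).
#' @param method see Details.
#' @param weights Wild Bootstrap weight scheme: `"normal"` (default,
#'   recommended), `"rademacher"`, or `"uniform"` on
#'   `[-sqrt(12)/2, sqrt(12)/2]`.
#' @param nboot bootstrap replications (default 10000).
#' @param seed integer seed for the bootstrap stream; the caller's RNG state
#'   is preserved. `NULL` continues the current stream.
#' @param boundary_fix if `TRUE`, markers with estimated AUC 0 or 1 are
#'   repaired by [apply_boundary_fix()] before inference; if `FALSE`
#'   (default) such markers are an error.
#' @param control,case,markers passed to [as_biomarker_data()].
#' @param wb_denominator combine the groupwise bootstrap variances as
#'   `v0*/n0 + v1*/n1` (`"paired"`, default) or with the group indices
#'   crossed, `v1*/n0 + v0*/n1` (`"crossed"`, kept for comparison; the two
#'   coincide for balanced groups).
#' @param prob_tol,maxpts accuracy of the multivariate-normal rectangle
#'   probabilities (methods `"mcp"`/`"logit"` and adjusted p-values).
#' @return an object of class `auc_select`; see [tidy.auc_select()],
#'   [glance.auc_select()], [autoplot.auc_select()].
#' @examples
#' fix <- make_icm_like_fixture(seed = 1)
#' fit <- auc_select(fix, status,
#'   control = "control", case = "case",
#'   auc0 = 0.8, method = "wb", nboot = 2000, seed = 42, boundary_fix = TRUE
#' )
#' tidy(fit)
#' @export
auc_select <- function(data, status = NULL, auc0, alpha = 0.025,
                       method = c("wb", "logit", "mcp", "bonferroni", "unadjusted", "efron"),
                       weights = c("normal", "rademacher", "uniform"),
                       nboot = 10000L, seed = NULL, boundary_fix = FALSE,
                       control = NULL, case = NULL, markers = NULL,
                       wb_denominator = c("paired", "crossed"),
                       prob_tol = 1e-6, maxpts = 25000L) {
  method <- match.arg(method)
  weights <- match.arg(weights)
  wb_denominator <- match.arg(wb_denominator)
  stopifnot(auc0 > 0, auc0 < 1, alpha > 0, alpha < 0.5, nboot >= 1)
  bd <- if (inherits(data, "biomarker_data")) {
    data
  } else {
    as_biomarker_data(data, {{ status }}, control = control, case = case, markers = markers)
  }

  tab <- placement_tables(bd)
  auc <- estimate_auc(tab)
  fixed <- character(0)
  if (any(auc <= 0 | auc >= 1)) {
    degen <- bd$marker_names[auc <= 0 | auc >= 1]
    if (!boundary_fix) {
      stop(
        "degenerate marker(s) with estimated AUC 0 or 1: ",
        paste(degen, collapse = ", "),
        ". The variance estimate is 0 and the logit undefined; re-run with ",
        "`boundary_fix = TRUE` to apply the conservative boundary replacement.",
        call. = FALSE
      )
    }
    bd <- apply_boundary_fix(bd)
    fixed <- degen
    tab <- placement_tables(bd)
    auc <- estimate_auc(tab)
  }
  cc <- estimate_cov(tab)
  v <- diag(cc$V_hat)
  N <- bd$N
  d <- bd$d
  Tl <- .test_statistics(auc, v, auc0, N)
  lg <- .logit_pieces(auc, v, auc0, N)

  draws <- NULL
  if (method %in% c("unadjusted", "bonferroni")) {
    crit <- stats::qnorm(1 - if (method == "bonferroni") alpha / d else alpha)
    statistic <- Tl
    lower <- pmin(pmax(auc - crit * sqrt(v / N), 0), 1)
    p <- 1 - stats::pnorm(Tl)
    if (method == "bonferroni") p <- pmin(1, d * p)
  } else if (method %in% c("mcp", "logit")) {
    crit <- equicoordinate_quantile(cc$R_hat, alpha, prob_tol = prob_tol, maxpts = maxpts)
    if (method == "mcp") {
      statistic <- Tl
      lower <- pmin(pmax(auc - crit * sqrt(v / N), 0), 1)
    } else {
      statistic <- lg$stat
      lower <- stats::plogis(stats::qlogis(auc) - crit * sqrt(lg$s / N))
    }
    p <- .mcp_p_values(statistic, cc$R_hat, prob_tol = prob_tol, maxpts = maxpts)
  } else {
    # resampling methods approximate the null law of the max statistic
    tb <- .rank_tables(bd$values, tab$i0, tab$i1)
    fit <- .core_fit(tb)
    A <- with_preserved_rng(
      {
        if (method == "wb") {
          .wb_max_stats(fit, nboot, scheme = weights, denominator = wb_denominator)
        } else {
          .efron_max_stats(bd$values, tab$i0, tab$i1, auc, nboot)
        }
      },
      seed = seed
    )
    crit <- sort(A)[ceiling((1 - alpha) * nboot)]
    statistic <- lg$stat
    # step-5 comparison: retention proportion of bootstrap max statistics at
    # or above the observed statistic; reported p = 1 - retention so that
    # small p means strong evidence
    p <- vapply(statistic, function(t) 1 - mean(t >= A), numeric(1))
    lower <- stats::plogis(stats::qlogis(auc) - crit * sqrt(lg$s / N))
    draws <- structure(
      list(
        max_stats = A, quantile = crit, nboot = as.integer(nboot),
        scheme = if (method == "wb") weights else "casewise"
      ),
      class = "bootstrap_draws"
    )
  }

  selected <- statistic >= crit
  res <- structure(
    list(
      markers = tibble::tibble(
        marker = bd$marker_names,
        auc = unname(auc),
        v_hat = unname(v),
        statistic = unname(statistic),
        lower = unname(lower),
        p_value = unname(p),
        selected = unname(selected),
        boundary_fixed = bd$marker_names %in% fixed
      ),
      method = method, alpha = alpha, auc0 = auc0,
      critical_value = unname(crit), global_reject = any(selected),
      R_hat = cc$R_hat, V_hat = cc$V_hat,
      n0 = bd$n0, n1 = bd$n1, N = N, d = d,
      weights = if (method == "wb") weights else NULL,
      nboot = if (!is.null(draws)) as.integer(nboot) else NULL,
      seed = seed, draws = draws, boundary_fixed = fixed
    ),
    class = "auc_select"
  )
  res
}

#' @export
print.auc_select <- function(x, ...) {
  cat("Simultaneous one-sided AUC inference (", x$method, ")\n", sep = "")
  cat(
    "  ", x$N, " subjects (", x$n0, " controls / ", x$n1, " cases), ",
    x$d, " markers; AUC0 = ", x$auc0, ", one-sided alpha = ", x$alpha, "\n",
    sep = ""
  )
  if (!is.null(x$nboot)) {
    cat("  ", x$nboot, " bootstrap draws (", x$draws$scheme, " weights)\n", sep = "")
  }
  cat("  critical value: ", format(x$critical_value, digits = 5), "\n", sep = "")
  if (length(x$boundary_fixed)) {
    cat(
      "  boundary fix applied to:",
      paste(x$boundary_fixed, collapse = ", "), "\n"
    )
  }
  print(x$markers)
  cat(
    "global null (all AUC <= AUC0):",
    if (x$global_reject) "REJECTED" else "not rejected", "\n"
  )
  invisible(x)
}
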