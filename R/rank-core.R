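#' Midranks of a numeric vector
#'
#' Ranks with ties resolved by averaging, i.e. the rank of a value is
#' (number of smaller values) + (number of equal values + 1) / 2. Midranks
#' realize the normalized empirical distribution function (the count
#' function taking values 0, 1/2, 1 at a tie), which is what makes the
#' rank-based AUC estimator valid for continuous, discrete and ordered
#' categorical data alike.
#'
#' @param x numeric (or ordered-factor) vector; ties allowed, `NA` not.
#' @return numeric vector of midranks; they always sum to `n (n + 1) / 2`.
#' @examples
#' midranks(c(1, 2, 2, 3)) # 1.0 2.5 2.5 4.0
#' @export
midranks <- function(x) {
  if (is.ordered(x) || is.factor(x)) x <- as.integer(x)
  if (!is.numeric(x)) {
    stop("midranks(): input must be numeric or an ordered factor", call. = FALSE)
  }
  if (length(x) < 1L) stop("midranks(): empty input", call. = FALSE)
  if (anyNA(x)) {
    stop("midranks(): input contains non-orderable values (NA/NaN)", call. = FALSE)
  }
  rank(x, ties.method = "average")
}

#' Construct a biomarker data object
#'
#' Bundles the subjects x markers measurement matrix of a within-subject
#' diagnostic trial (every test performed on every subject) with the binary
#' gold-standard status. Controls are coded 0, cases 1.
#'
#' @param values numeric matrix, `N` subjects x `d` markers. Ordered factors
#'   in a data frame input are mapped to their category codes; any
#'   order-preserving coding is equivalent because all downstream statistics
#'   are rank-based.
#' @param status integer/logical vector of length `N`; 0 = control, 1 = case.
#' @param marker_names optional character vector of length `d`.
#' @return an object of class `biomarker_data`: a list with elements
#'   `values`, `status`, `marker_names`, `n0`, `n1`, `N`, `d`.
#' @export
biomarker_data <- function(values, status, marker_names = NULL) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  status <- as.integer(status)
  if (nrow(values) != length(status)) {
    stop("`values` and `status` disagree on the number of subjects", call. = FALSE)
  }
  if (anyNA(values) || anyNA(status)) {
    bad <- which(is.na(values), arr.ind = TRUE)
    stop("missing values are not supported (within-subject design): ",
      if (nrow(bad)) {
        paste0("row ", bad[, 1], ", marker column ", bad[, 2], collapse = "; ")
      } else "status contains NA",
      call. = FALSE
    )
  }
  if (!all(status %in% c(0L, 1L))) {
    stop("`status` must only contain 0 (control) and 1 (case)", call. = FALSE)
  }
  n0 <- sum(status == 0L)
  n1 <- sum(status == 1L)
  if (n0 < 2L || n1 < 2L) {
    stop("need at least 2 controls and 2 cases (variance estimation divides by n_i - 1); got ",
      n0, " controls, ", n1, " cases",
      call. = FALSE
    )
  }
  if (is.null(marker_names)) {
    marker_names <- colnames(values) %||% paste0("marker_", seq_len(ncol(values)))
  }
  colnames(values) <- marker_names
  structure(
    list(
      values = values, status = status, marker_names = marker_names,
      n0 = n0, n1 = n1, N = n0 + n1, d = ncol(values)
    ),
    class = "biomarker_data"
  )
}

#' Coerce a data frame to a biomarker data object
#'
#' @param data a data frame with one row per subject, or an existing
#'   `biomarker_data` object (returned unchanged).
#' @param status the status column, as a bare name or string.
#' @param control,case labels in the status column mapped to control/case.
#'   May be omitted when the column is already coded 0/1 or logical.
#' @param markers optional character vector naming the marker columns;
#'   defaults to every column except the status column, in file order.
#' @return a [biomarker_data()] object.
#' @export
as_biomarker_data <- function(data, status, control = NULL, case = NULL,
                              markers = NULL) {
  if (inherits(data, "biomarker_data")) {
    return(data)
  }
  data <- as.data.frame(data)
  status_col <- rlang::as_name(rlang::ensym(status))
  if (!status_col %in% names(data)) {
    stop("status column `", status_col, "` not found", call. = FALSE)
  }
  raw <- data[[status_col]]
  if (is.null(control) && is.null(case)) {
    if (is.logical(raw)) {
      st <- as.integer(raw)
    } else if (all(raw %in% c(0, 1))) {
      st <- as.integer(raw)
    } else {
      stop("status column is not coded 0/1; supply `control` and `case` labels",
        call. = FALSE
      )
    }
  } else {
    raw <- as.character(raw)
    unknown <- setdiff(unique(raw), c(control, case))
    if (length(unknown)) {
      stop("unknown status label(s): ", paste(unknown, collapse = ", "),
        call. = FALSE
      )
    }
    st <- ifelse(raw %in% case, 1L, 0L)
  }
  if (is.null(markers)) markers <- setdiff(names(data), status_col)
  vals <- data[markers]
  for (j in seq_along(vals)) {
    if (is.factor(vals[[j]])) {
      vals[[j]] <- as.integer(vals[[j]])
    } else if (!is.numeric(vals[[j]])) {
      stop("marker column `", markers[j], "` is neither numeric nor a factor",
        call. = FALSE
      )
    }
  }
  na_cells <- which(is.na(as.matrix(vals)), arr.ind = TRUE)
  if (nrow(na_cells)) {
    stop(
      "missing values in marker columns: ",
      paste0("row ", na_cells[, 1], ", column `", markers[na_cells[, 2]], "`",
        collapse = "; "
      ),
      call. = FALSE
    )
  }
  biomarker_data(as.matrix(vals), st, marker_names = markers)
}

#' @export
print.biomarker_data <- function(x, ...) {
  cat(
    "<biomarker_data> ", x$N, " subjects (", x$n0, " controls, ", x$n1,
    " cases), ", x$d, " marker", if (x$d > 1) "s", "\n",
    sep = ""
  )
  cat("markers:", paste(x$marker_names, collapse = ", "), "\n")
  invisible(x)
}

## ---- internal fast path ------------------------------------------------
## The simulation engine calls these thousands of times; they work on bare
## matrices with controls/cases index vectors and avoid any data-frame or
## S3 overhead.

.rank_tables <- function(X, i0, i1) {
  N <- nrow(X)
  n0 <- length(i0)
  n1 <- length(i1)
  Rp <- apply(X, 2L, rank, ties.method = "average")
  Ri <- matrix(0, N, ncol(X))
  Ri[i0, ] <- apply(X[i0, , drop = FALSE], 2L, rank, ties.method = "average")
  Ri[i1, ] <- apply(X[i1, , drop = FALSE], 2L, rank, ties.method = "average")
  Z <- matrix(0, N, ncol(X))
  # placement of a subject = pooled midrank minus internal midrank, scaled
  # by the size of the *opposite* group
  Z[i0, ] <- (Rp[i0, , drop = FALSE] - Ri[i0, , drop = FALSE]) / n1
  Z[i1, ] <- (Rp[i1, , drop = FALSE] - Ri[i1, , drop = FALSE]) / n0
  list(
    Rp = Rp, Ri = Ri, Z = Z, i0 = i0, i1 = i1,
    n0 = n0, n1 = n1, N = N, d = ncol(X)
  )
}

.core_fit <- function(tb) {
  Z0 <- tb$Z[tb$i0, , drop = FALSE]
  Z1 <- tb$Z[tb$i1, , drop = FALSE]
  m0 <- colMeans(Z0)
  m1 <- colMeans(Z1)
  V0 <- stats::cov(Z0)
  V1 <- stats::cov(Z1)
  V <- tb$N * (V0 / tb$n0 + V1 / tb$n1)
  list(
    auc = m1, V = V, V0 = V0, V1 = V1, m0 = m0, m1 = m1,
    Z0c = sweep(Z0, 2L, m0), Z1c = sweep(Z1, 2L, m1)
  )
}

## ---- user-facing surface ----------------------------------------------

#' Pooled midranks, internal ranks and placements
#'
#' Computes, per marker, the pooled midranks over all subjects, the internal
#' midranks within each status group, and the normed placements
#' `Z = (pooled - internal) / (N - n_i)`. A case placement is the empirical
#' control distribution function evaluated at that case's value (and vice
#' versa), so the mean of the case placements is the rank-form AUC estimate.
#'
#' @param data a `biomarker_data` object (see [as_biomarker_data()]).
#' @return an object of class `placement_tables` with elements
#'   `pooled_midranks`, `internal_ranks`, `placements` (all `N x d`),
#'   `group_placement_means` (`2 x d`, rows "control" and "case"), and the
#'   design constants `n0`, `n1`, `N`, `d`, `marker_names`, plus the group
#'   index vectors `i0`, `i1`.
#' @export
placement_tables <- function(data) {
  stopifnot(inherits(data, "biomarker_data"))
  tb <- .rank_tables(data$values, which(data$status == 0L), which(data$status == 1L))
  gm <- rbind(
    control = colMeans(tb$Z[tb$i0, , drop = FALSE]),
    case = colMeans(tb$Z[tb$i1, , drop = FALSE])
  )
  colnames(gm) <- data$marker_names
  structure(
    list(
      pooled_midranks = tb$Rp, internal_ranks = tb$Ri, placements = tb$Z,
      group_placement_means = gm, i0 = tb$i0, i1 = tb$i1,
      n0 = tb$n0, n1 = tb$n1, N = tb$N, d = tb$d,
      marker_names = data$marker_names
    ),
    class = "placement_tables"
  )
}

#' Rank-form AUC estimates
#'
#' The midrank estimator `(mean case rank - mean control rank) / N + 1/2`,
#' identical to the mean of the case placements and to the normalized
#' Mann-Whitney kernel `P(X0 < X1) + P(X0 = X1) / 2` evaluated on the
#' empirical distributions. Invariant under strictly monotone
#' transformations of any marker.
#'
#' @param tables a [placement_tables()] object.
#' @return named numeric vector of length `d` with values in `[0, 1]`.
#' @export
estimate_auc <- function(tables) {
  stopifnot(inherits(tables, "placement_tables"))
  stats::setNames(tables$group_placement_means["case", ], tables$marker_names)
}

#' Covariance and correlation estimates for the AUC vector
#'
#' Estimates the asymptotic covariance of `sqrt(N) * (AUC-hat - AUC)` from
#' the groupwise sample covariances of the placements:
#' `V-hat = N * (V0 / n0 + V1 / n1)`. A marker whose estimated AUC is 0 or 1
#' has constant placements, hence a zero diagonal entry; such markers are
#' flagged `degenerate` (not an error here; the inference layer applies the
#' boundary policy).
#'
#' @param tables a [placement_tables()] object.
#' @return an object of class `cov_corr`: list with `V_hat` (`d x d`),
#'   `V_hat_group` (list of the two groupwise `d x d` matrices),
#'   `R_hat` (correlation, `NA` rows for degenerate markers), and
#'   `degenerate` (logical `d`-vector).
#' @export
estimate_cov <- function(tables) {
  stopifnot(inherits(tables, "placement_tables"))
  Z0 <- tables$placements[tables$i0, , drop = FALSE]
  Z1 <- tables$placements[tables$i1, , drop = FALSE]
  V0 <- stats::cov(Z0)
  V1 <- stats::cov(Z1)
  V <- tables$N * (V0 / tables$n0 + V1 / tables$n1)
  dimnames(V) <- list(tables$marker_names, tables$marker_names)
  v <- diag(V)
  degen <- v <= 0
  R <- matrix(NA_real_, tables$d, tables$d, dimnames = dimnames(V))
  ok <- !degen
  if (any(ok)) {
    R[ok, ok] <- stats::cov2cor(V[ok, ok, drop = FALSE])
  }
  structure(
    list(
      V_hat = V, V_hat_group = list(control = V0, case = V1),
      R_hat = R, degenerate = stats::setNames(degen, tables$marker_names)
    ),
    class = "cov_corr"
  )
}

#' Per-marker AUC estimates as a tibble
#'
#' Convenience wrapper: estimates each marker's AUC, its variance component
#' `v-hat` (the diagonal of the covariance estimate, so that
#' `se = sqrt(v-hat / N)`), and flags degenerate markers.
#'
#' @inheritParams as_biomarker_data
#' @return a tibble with columns `marker`, `auc`, `v_hat`, `se`,
#'   `degenerate`.
#' @examples
#' df <- make_icm_like_fixture(seed = 1)
#' auc_estimate(df, status, control = "control", case = "case")
#' @export
auc_estimate <- function(data, status, control = NULL, case = NULL,
                         markers = NULL) {
  bd <- if (inherits(data, "biomarker_data")) {
    data
  } else {
    as_biomarker_data(data, {{ status }}, control = control, case = case, markers = markers)
  }
  tab <- placement_tables(bd)
  auc <- estimate_auc(tab)
  cc <- estimate_cov(tab)
  v <- diag(cc$V_hat)
  tibble::tibble(
    marker = bd$marker_names,
    auc = unname(auc),
    v_hat = unname(v),
    se = sqrt(unname(v) / bd$N),
    degenerate = unname(cc$degenerate)
  )
}
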