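test_that("studentized statistic matches the hand-computed toy value", {
  # controls {1,3}, cases {2,4}: AUC-hat 0.75, placements {0, .5} / {.5, 1},
  # groupwise variances 1/8 each, v-hat = 4 (1/16 + 1/16) = 1/2,
  # T = (0.75 - 0.5) sqrt(4 / 0.5) = sqrt(2) / 2
  bd <- toy_data()
  fit <- auc_select(bd, auc0 = 0.5, method = "unadjusted")
  expect_equal(fit$markers$statistic, sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(fit$markers$v_hat, 0.5)
  # statistic is zero exactly at the threshold
  fit0 <- auc_select(bd, auc0 = 0.75, method = "unadjusted")
  expect_equal(fit0$markers$statistic, 0)
})

test_that("logit statistics use the delta-method variance and keep the sign of the raw ones", {
  set.seed(21)
  bd <- random_normal_data(20, 20, d = 3, delta = 0.8)
  raw <- auc_select(bd, auc0 = 0.7, method = "mcp")
  lgt <- auc_select(bd, auc0 = 0.7, method = "logit")
  expect_equal(sign(raw$markers$statistic), sign(lgt$markers$statistic))

  # at AUC-hat = 1/2 the Jacobian factor is 4, so s-hat = 16 v-hat;
  # construct AUC-hat = 1/2 exactly and compare statistics analytically
  bd2 <- biomarker_data(matrix(c(1, 2, 3, 4, 1, 2, 3, 4)), rep(c(0L, 1L), each = 4))
  tab <- placement_tables(bd2)
  expect_equal(unname(estimate_auc(tab)), 0.5)
  v <- diag(estimate_cov(tab)$V_hat)
  f <- auc_select(bd2, auc0 = 0.25, method = "logit")
  s_expected <- 16 * v
  expect_equal(
    f$markers$statistic,
    unname((qlogis(0.5) - qlogis(0.25)) * sqrt(8 / s_expected))
  )
})

test_that("equicoordinate quantile reproduces its closed-form limits", {
  # d = 1: the standard normal quantile
  expect_equal(equicoordinate_quantile(diag(1), 0.025), qnorm(0.975), tolerance = 1e-9)
  # independence, d = 2: z with Phi(z)^2 = 1 - alpha (independent oracle)
  z_oracle <- uniroot(function(z) pnorm(z)^2 - 0.975, c(1, 4), tol = 1e-10)$root
  expect_equal(equicoordinate_quantile(diag(2), 0.025), z_oracle, tolerance = 1e-4)
  # comonotone limit: any dimension collapses to the univariate quantile
  R1 <- matrix(1, 4, 4)
  expect_equal(equicoordinate_quantile(R1, 0.025), qnorm(0.975), tolerance = 1e-9)
  # determinism across calls
  R <- matrix(0.6, 3, 3)
  diag(R) <- 1
  expect_identical(
    equicoordinate_quantile(R, 0.025),
    equicoordinate_quantile(R, 0.025)
  )
})

test_that("equicoordinate quantile is monotone in dimension and in correlation", {
  qs_d <- vapply(1:4, function(d) equicoordinate_quantile(diag(d), 0.025), numeric(1))
  expect_true(all(diff(qs_d) > 0))
  qs_rho <- vapply(c(0, 0.3, 0.6, 0.9, 0.99), function(r) {
    R <- matrix(r, 5, 5)
    diag(R) <- 1
    equicoordinate_quantile(R, 0.025)
  }, numeric(1))
  expect_true(all(diff(qs_rho) < 1e-4)) # non-increasing up to integration tol
  expect_gt(qs_rho[1], qnorm(0.975))
  expect_lt(abs(qs_rho[5] - qnorm(0.975)), 0.12)
})

test_that("invalid correlation matrices are rejected, near-singular ones are not", {
  M <- matrix(c(1, 0.5, 0.2, 1), 2, 2)
  expect_error(equicoordinate_quantile(M, 0.025), "not symmetric")
  D <- diag(c(1, 2))
  expect_error(equicoordinate_quantile(D, 0.025), "unit diagonal")
  bad <- matrix(c(1, -1, -1, -1, 1, -1, -1, -1, 1), 3, 3) # not PSD
  expect_error(equicoordinate_quantile(bad, 0.025), "positive semidefinite")
  nearly <- matrix(0.999999, 3, 3)
  diag(nearly) <- 1
  expect_error(equicoordinate_quantile(nearly, 0.025), NA)
})

test_that("lower bounds order as unadjusted >= MCP >= Bonferroni, with equality at d = 1", {
  set.seed(22)
  for (i in 1:5) {
    bd <- random_normal_data(18, 15, d = 4, rho = runif(1, 0, 0.9), delta = runif(1, 0.3, 1.5))
    un <- auc_select(bd, auc0 = 0.6, method = "unadjusted")$markers$lower
    mc <- auc_select(bd, auc0 = 0.6, method = "mcp")$markers$lower
    bo <- auc_select(bd, auc0 = 0.6, method = "bonferroni")$markers$lower
    expect_true(all(un >= mc - 1e-10))
    expect_true(all(mc >= bo - 1e-10))
  }
  bd1 <- random_normal_data(15, 15, d = 1)
  expect_equal(
    auc_select(bd1, auc0 = 0.6, method = "unadjusted")$markers$lower,
    auc_select(bd1, auc0 = 0.6, method = "bonferroni")$markers$lower
  )
  expect_equal(
    auc_select(bd1, auc0 = 0.6, method = "unadjusted")$markers$lower,
    auc_select(bd1, auc0 = 0.6, method = "mcp")$markers$lower,
    tolerance = 1e-6
  )
})

test_that("logit bounds stay inside (0, 1) and approach the raw MCP bounds as N grows", {
  set.seed(23)
  bd <- random_normal_data(12, 12, d = 2, delta = 0.5)
  f <- auc_select(bd, auc0 = 0.6, method = "logit")
  expect_true(all(f$markers$lower > 0 & f$markers$lower < 1))
  expect_true(all(f$markers$lower < f$markers$auc))

  gap <- function(n) {
    bd <- random_normal_data(n, n, d = 2, rho = 0.5, delta = 1)
    max(abs(
      auc_select(bd, auc0 = 0.6, method = "logit")$markers$lower -
        auc_select(bd, auc0 = 0.6, method = "mcp")$markers$lower
    ))
  }
  set.seed(24)
  expect_lt(gap(2000), 0.01)
  # delta-method agreement: the discrepancy shrinks with N
  set.seed(24)
  g_small <- gap(60)
  set.seed(24)
  g_large <- gap(2000)
  expect_lt(g_large, g_small)
})

test_that("boundary fix performs the documented minimal replacement", {
  # controls {1,2}, cases {3,4}: replace the largest control with the
  # smallest case -> controls {1,3}, AUC drops from 1 to 0.875
  bd <- biomarker_data(matrix(c(1, 2, 3, 4)), c(0L, 0L, 1L, 1L), "m")
  fx <- apply_boundary_fix(bd)
  expect_equal(sort(fx$values[fx$status == 0L, 1]), c(1, 3))
  expect_equal(unname(estimate_auc(placement_tables(fx))), 0.875)

  # mirror case: AUC = 0, smallest case replaced by largest control
  bd0 <- biomarker_data(matrix(c(3, 4, 1, 2)), c(0L, 0L, 1L, 1L), "m")
  fx0 <- apply_boundary_fix(bd0)
  a0 <- unname(estimate_auc(placement_tables(fx0)))
  expect_gt(a0, 0)
  expect_lt(a0, 1)

  # non-degenerate marker: warning and no-op
  bd2 <- toy_data()
  expect_warning(fx2 <- apply_boundary_fix(bd2, marker = 1), "not degenerate")
  expect_identical(fx2$values, bd2$values)
})

test_that("degenerate markers error with a named message unless the fix is requested", {
  sep <- biomarker_data(
    cbind(bad = c(1, 2, 8, 9), ok = c(1, 3, 2, 4)),
    c(0L, 0L, 1L, 1L)
  )
  expect_error(auc_select(sep, auc0 = 0.5, method = "logit"), "bad")
  fit <- auc_select(sep, auc0 = 0.5, method = "logit", boundary_fix = TRUE)
  expect_true(fit$markers$boundary_fixed[1])
  expect_lt(fit$markers$auc[1], 1)
})

test_that("test decisions, confidence bounds and p-values select the same markers for every method", {
  set.seed(25)
  for (method in c("unadjusted", "bonferroni", "mcp", "logit", "wb")) {
    bd <- random_normal_data(20, 16, d = 3, rho = 0.7, delta = 1.1)
    fit <- auc_select(bd,
      auc0 = 0.72, method = method, nboot = 500, seed = 99
    )
    m <- fit$markers
    expect_identical(m$selected, m$statistic >= fit$critical_value)
    expect_identical(m$selected, m$lower > fit$auc0)
    expect_identical(m$selected, m$p_value <= fit$alpha)
    expect_identical(fit$global_reject, any(m$selected))
  }
})

test_that("tidy, glance and autoplot expose the fit", {
  set.seed(26)
  bd <- random_normal_data(15, 15, d = 2, delta = 1)
  fit <- auc_select(bd, auc0 = 0.6, method = "logit")
  td <- tidy(fit)
  expect_s3_class(td, "tbl_df")
  expect_named(
    td,
    c("marker", "auc", "v_hat", "statistic", "lower", "p_value", "selected", "boundary_fixed")
  )
  gl <- glance(fit)
  expect_equal(nrow(gl), 1L)
  expect_equal(gl$n_selected, sum(td$selected))
  p <- ggplot2::ggplot_build(autoplot(fit))
  expect_s3_class(p, "ggplot_built")
})
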