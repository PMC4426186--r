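## broom-style accessors and plotting for auc_select fits.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Per-marker results of an AUC selection fit
#'
#' @param x an [auc_select()] object.
#' @param ... unused.
#' @return a tibble with one row per marker: `marker`, `auc`, `v_hat`,
#'   `statistic`, `lower` (one-sided simultaneous lower confidence bound;
#'   the upper bound is 1), `p_value` (adjusted), `selected`,
#'   `boundary_fixed`.
#' @export
tidy.auc_select <- function(x, ...) {
  x$markers
}

#' One-row summary of an AUC selection fit
#'
#' @param x an [auc_select()] object.
#' @param ... unused.
#' @return a one-row tibble: method and design constants, the critical
#'   value, the number of selected markers and the global decision.
#' @export
glance.auc_select <- function(x, ...) {
  tibble::tibble(
    method = x$method, auc0 = x$auc0, alpha = x$alpha,
    critical_value = x$critical_value,
    n_control = x$n0, n_case = x$n1, n_markers = x$d,
    nboot = x$nboot %||% NA_integer_,
    n_selected = sum(x$markers$selected),
    global_reject = x$global_reject
  )
}

#' Plot simultaneous lower confidence bounds against the threshold
#'
#' One row per marker: the AUC estimate (point) with its one-sided
#' simultaneous confidence interval extending from the lower bound to 1,
#' and the selection threshold `auc0` as a dashed line. Markers whose whole
#' interval lies above the threshold are the selected ones.
#'
#' @param object an [auc_select()] object.
#' @param ... unused.
#' @return a ggplot.
#' @export
autoplot.auc_select <- function(object, ...) {
  df <- object$markers
  ggplot2::ggplot(df, ggplot2::aes(
    x = stats::reorder(.data$marker, .data$auc),
    y = .data$auc, colour = .data$selected
  )) +
    ggplot2::geom_linerange(ggplot2::aes(ymin = .data$lower, ymax = 1), linewidth = 0.8) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::geom_hline(yintercept = object$auc0, linetype = "dashed") +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "#2166ac", `FALSE` = "#b2182b"),
      labels = c(`TRUE` = "selected", `FALSE` = "not selected"),
      name = NULL
    ) +
    ggplot2::coord_flip(ylim = c(0, 1)) +
    ggplot2::labs(
      x = NULL,
      y = sprintf(
        "AUC with one-sided %g%% simultaneous lower bound (%s)",
        100 * (1 - object$alpha), object$method
      )
    ) +
    ggplot2::theme_minimal()
}
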