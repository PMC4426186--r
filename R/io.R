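## CSV input, TSV report output, scenario files, and the functions behind
## the command-line wrappers in inst/cli/.

#' Read a biomarker CSV file
#'
#' Expects an RFC-4180 CSV with a header row, one row per subject, one
#' status column, and marker measurements in the remaining (numeric or
#' ordinal) columns. Column order in the file is preserved.
#'
#' @param path file path.
#' @param status_col name of the status column.
#' @param control_label,case_label values of the status column denoting
#'   controls and cases (defaults `"0"` / `"1"`).
#' @return a [biomarker_data()] object.
#' @export
read_biomarker_csv <- function(path, status_col = "status",
                               control_label = "0", case_label = "1") {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!status_col %in% names(df)) {
    stop("status column `", status_col, "` not found in ", path, call. = FALSE)
  }
  as_biomarker_data(df,
    status = !!rlang::sym(status_col),
    control = control_label, case = case_label
  )
}

#' Write an analysis report as TSV
#'
#' One row per marker (name, AUC estimate, simultaneous one-sided lower
#' confidence bound, adjusted p-value, selection flag), preceded by
#' `#`-prefixed metadata lines recording the method, level, threshold,
#' bootstrap settings, seed and any boundary fixes — a diffable plain-text
#' record of the analysis.
#'
#' @param fit an [auc_select()] result.
#' @param path output path.
#' @param digits significant digits for bounds and p-values (default 6).
#' @param full_precision write full double precision instead.
#' @return `path`, invisibly.
#' @export
write_report <- function(fit, path, digits = 6, full_precision = FALSE) {
  stopifnot(inherits(fit, "auc_select"))
  meta <- c(
    paste0("# method: ", fit$method),
    paste0("# alpha_one_sided: ", fit$alpha),
    paste0("# auc0: ", fit$auc0),
    paste0("# critical_value: ", format(fit$critical_value, digits = 10)),
    if (!is.null(fit$weights)) paste0("# weights: ", fit$weights),
    if (!is.null(fit$nboot)) paste0("# nboot: ", fit$nboot),
    if (!is.null(fit$seed)) paste0("# seed: ", fit$seed),
    paste0(
      "# boundary_fixed: ",
      if (length(fit$boundary_fixed)) paste(fit$boundary_fixed, collapse = ",") else "none"
    ),
    paste0("# n_control: ", fit$n0, "  n_case: ", fit$n1)
  )
  tab <- fit$markers[, c("marker", "auc", "lower", "p_value", "selected")]
  if (!full_precision) {
    tab <- dplyr::mutate(tab, dplyr::across(c("auc", "lower", "p_value"), ~ signif(.x, digits)))
  }
  writeLines(meta, path)
  readr::write_tsv(tab, path, append = TRUE, col_names = TRUE)
  invisible(path)
}

#' Analyse a biomarker CSV end to end
#'
#' Thin composition of [read_biomarker_csv()], [auc_select()] and
#' [write_report()]; this is what the `auc-select` command-line wrapper
#' calls. Validation failures are errors (the CLI maps them to a nonzero
#' exit status).
#'
#' @inheritParams read_biomarker_csv
#' @inheritParams auc_select
#' @param input input CSV path.
#' @param output optional TSV report path.
#' @param full_precision see [write_report()].
#' @return the [auc_select()] fit, invisibly.
#' @export
run_analysis <- function(input, status_col, auc0, alpha = 0.025,
                         method = "wb", weights = "normal", nboot = 10000L,
                         seed = NULL, boundary_fix = FALSE,
                         control_label = "0", case_label = "1",
                         output = NULL, full_precision = FALSE) {
  bd <- read_biomarker_csv(input, status_col, control_label, case_label)
  message(
    "analysing ", input, ": ", bd$N, " subjects (", bd$n0, " controls / ",
    bd$n1, " cases), ", bd$d, " markers; method=", method,
    if (!is.null(seed)) paste0(", seed=", seed)
  )
  fit <- auc_select(bd,
    auc0 = auc0, alpha = alpha, method = method,
    weights = weights, nboot = nboot, seed = seed, boundary_fix = boundary_fix
  )
  if (length(fit$boundary_fixed)) {
    message("boundary fix applied to: ", paste(fit$boundary_fixed, collapse = ", "))
  }
  if (!is.null(output)) {
    write_report(fit, output, full_precision = full_precision)
    message("report written to ", output)
  }
  invisible(fit)
}

#' Read simulation scenarios from a YAML file
#'
#' The file holds either a single mapping of [sim_scenario()] fields or a
#' top-level `scenarios:` sequence of such mappings.
#'
#' @param path YAML file path.
#' @return a list of `sim_scenario` objects.
#' @export
read_scenario_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  raw <- if (!is.null(y$scenarios)) y$scenarios else list(y)
  lapply(raw, function(cfg) {
    # YAML 1.1 reads a bare `N` key as a boolean; map it back
    names(cfg)[names(cfg) %in% c("FALSE", "no")] <- "N"
    known <- names(formals(sim_scenario))
    bad <- setdiff(names(cfg), known)
    if (length(bad)) {
      stop("unknown scenario field(s) in ", path, ": ",
        paste(bad, collapse = ", "),
        call. = FALSE
      )
    }
    do.call(sim_scenario, cfg)
  })
}

#' Run scenarios from a YAML file and append results to a TSV
#'
#' Results accumulate one row per scenario x method. Re-running with the
#' same output file skips scenario ids that already have rows, so an
#' interrupted sweep can resume.
#'
#' @param scenario_file YAML scenario file (see [read_scenario_yaml()]).
#' @param output results TSV path.
#' @param progress forwarded to [run_study()].
#' @return the full results tibble, invisibly.
#' @export
run_simulation_file <- function(scenario_file, output, progress = TRUE) {
  scenarios <- read_scenario_yaml(scenario_file)
  done <- if (file.exists(output)) {
    readr::read_tsv(output, show_col_types = FALSE, progress = FALSE)
  } else {
    NULL
  }
  res <- done
  for (sc in scenarios) {
    if (!is.null(done) && sc$id %in% done$id) {
      message("skipping already-computed scenario ", sc$id)
      next
    }
    message("running scenario ", sc$id, " (nsim ", sc$nsim, ")")
    row <- dplyr::select(run_study(sc, progress = progress), -"marker_rates")
    res <- dplyr::bind_rows(res, row)
    readr::write_tsv(res, output)
  }
  invisible(res)
}
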