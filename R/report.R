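# End-to-end driver: simulate or load a cohort, evaluate the equation panel,
# run every comparison, and write the report bundle (descriptives,
# concordance, staging, Bland-Altman curve data, run manifest).

#' Run configuration for the report pipeline
#'
#' @param input path to a cohort file (CSV/XLS/XLSX), or `NULL` to simulate.
#' @param params [cohort_params()] used when simulating (ignored with `input`).
#' @param col_map,units passed to [read_cohort()] when loading a file.
#' @param equations equation variant ids to evaluate (default: all nine).
#' @param comparisons ordered (reference, predictor) pairs; default
#'   [default_comparisons()].
#' @param agreement_method `"linear_regression"` (default), `"classic"` or
#'   `"quantile_regression"`, applied to every pair.
#' @param loa_multiplier SD multiplier for the limits of agreement (2 by
#'   default; 1.96 for exact normal 95% limits).
#' @param margins accuracy margins, default `c(0.10, 0.30)`.
#' @param cutoff_stages staging dichotomization cut-offs, default `c(2, 3)`.
#' @param stratify_by stratification column, default `"hiv_status"`.
#' @param seed RNG seed for simulation.
#' @param output_dir where [run_report()] writes the bundle.
#' @return a list of class `run_config`.
#' @export
report_config <- function(input = NULL,
                          params = cohort_params(),
                          col_map = NULL,
                          units = list(scr = "mg/dL", scysc = "mg/L"),
                          equations = egfr_equations()$equation,
                          comparisons = default_comparisons(),
                          agreement_method = c("linear_regression", "classic",
                                               "quantile_regression"),
                          loa_multiplier = 2,
                          margins = c(0.10, 0.30),
                          cutoff_stages = c(2, 3),
                          stratify_by = "hiv_status",
                          seed = 1L,
                          output_dir = "egfr_report") {
  agreement_method <- match.arg(agreement_method)
  bad <- setdiff(unique(c(comparisons$reference, comparisons$predictor)),
                 equations)
  if (length(bad) > 0) {
    stop("comparisons reference undeclared equation(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  structure(list(input = input, params = params, col_map = col_map,
                 units = units, equations = equations,
                 comparisons = comparisons,
                 agreement_method = agreement_method,
                 loa_multiplier = loa_multiplier, margins = margins,
                 cutoff_stages = cutoff_stages, stratify_by = stratify_by,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "run_config")
}

#' Run the full comparison pipeline and write the report bundle
#'
#' Loads (or simulates) the cohort, evaluates the equation panel, and writes
#' to `config$output_dir`: `descriptives.csv`, `concordance.csv`,
#' `staging.csv`, `agreement_curves.csv` (the plot-data contract for
#' Bland-Altman figures), `exclusions.csv` and `manifest.json` (config echo,
#' seed, package version, row counts). Any stage failure removes the partial
#' bundle and aborts with a stage-named error. Identical config and seed give
#' byte-identical outputs.
#'
#' @param config a [report_config()].
#' @return invisibly, a list with the in-memory tables (`cohort`, `panel`,
#'   `descriptives`, `concordance`, `staging`, `agreement_curves`,
#'   `manifest`).
#' @export
run_report <- function(config = report_config()) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$output_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  stage <- "setup"
  res <- tryCatch({
    stage <- "cohort"
    cohort <- if (is.null(config$input)) {
      generate_cohort(config$params, seed = config$seed)
    } else {
      read_cohort(config$input, col_map = config$col_map,
                  units = config$units)
    }

    stage <- "panel"
    panel <- egfr_panel(cohort, config$equations,
                        carry = config$stratify_by)

    stage <- "descriptives"
    descr <- cohort_descriptives(cohort)

    stage <- "concordance"
    conc <- concordance_table(panel, config$comparisons,
                              stratify_by = config$stratify_by,
                              margins = config$margins)

    stage <- "staging"
    stag <- staging_table(panel, config$comparisons,
                          cutoff_stages = config$cutoff_stages)

    stage <- "agreement"
    curves <- dplyr::bind_rows(lapply(seq_len(nrow(config$comparisons)),
      function(i) {
        ref <- config$comparisons$reference[i]
        prd <- config$comparisons$predictor[i]
        pe <- pair_estimates(panel, ref, prd,
                             stratify_by = config$stratify_by)
        curve <- switch(config$agreement_method,
          classic = ba_classic(pe, multiplier = config$loa_multiplier),
          linear_regression = ba_regression(pe,
                                            multiplier = config$loa_multiplier),
          quantile_regression = ba_quantile(pe))
        tibble::add_column(tibble::as_tibble(curve),
                           reference = ref, predictor = prd, .before = 1)
      }))

    stage <- "write"
    wf <- function(x, name) {
      p <- file.path(config$output_dir, name)
      readr::write_csv(x, p, progress = FALSE)
      written <<- c(written, p)
      p
    }
    wf(descr, "descriptives.csv")
    wf(conc, "concordance.csv")
    wf(stag, "staging.csv")
    wf(curves, "agreement_curves.csv")
    wf(cohort_exclusions(cohort), "exclusions.csv")

    manifest <- list(
      package = "egfragree",
      version = as.character(packageVersion("egfragree")),
      seed = config$seed,
      input = config$input %||% "simulated",
      params = if (is.null(config$input)) unclass(config$params) else NULL,
      equations = config$equations,
      comparisons = config$comparisons,
      agreement_method = config$agreement_method,
      loa_multiplier = config$loa_multiplier,
      margins = config$margins,
      cutoff_stages = config$cutoff_stages,
      stratify_by = config$stratify_by,
      n_subjects = nrow(cohort),
      n_excluded = nrow(cohort_exclusions(cohort)))
    mp <- file.path(config$output_dir, "manifest.json")
    jsonlite::write_json(manifest, mp, auto_unbox = TRUE, pretty = TRUE,
                         digits = NA)
    written <- c(written, mp)

    list(cohort = cohort, panel = panel, descriptives = descr,
         concordance = conc, staging = stag, agreement_curves = curves,
         manifest = manifest)
  }, error = function(e) {
    unlink(written)
    stop("report pipeline failed at stage '", stage, "': ",
         conditionMessage(e), call. = FALSE)
  })
  invisible(res)
}
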