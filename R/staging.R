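# CKD staging from eGFR and between-formula staging discrepancies.
#
# Stages follow the standard five-band ladder on eGFR alone (no albuminuria
# criterion): stage 1 >= 90, stage 2 in [60, 90), stage 3 in [30, 60),
# stage 4 in [15, 30), stage 5 < 15 mL/min/1.73 m2. Intervals are closed
# below and open above, so 60.0 is stage 2 and 59.999 is stage 3.

#' Default CKD stage thresholds
#'
#' Strictly decreasing eGFR breakpoints (mL/min/1.73 m2) separating stages
#' 1|2, 2|3, 3|4 and 4|5.
#'
#' @return numeric vector `c(90, 60, 30, 15)`.
#' @export
stage_thresholds <- function() c(90, 60, 30, 15)

#' CKD stage from eGFR
#'
#' @param egfr numeric vector of eGFR values (> 0), mL/min/1.73 m2.
#' @param thresholds strictly decreasing positive breakpoints; see
#'   [stage_thresholds()].
#' @return integer vector of stages in 1..5.
#' @examples
#' ckd_stage(c(95, 90, 89.999, 60, 59.9, 15, 14.9))  # 1 1 2 2 3 4 5
#' @export
ckd_stage <- function(egfr, thresholds = stage_thresholds()) {
  stopifnot(length(thresholds) == 4, all(diff(thresholds) < 0),
            all(thresholds > 0))
  if (any(!is.na(egfr) & (!is.finite(egfr) | egfr <= 0))) {
    stop("eGFR must be positive and finite for staging", call. = FALSE)
  }
  as.integer(length(thresholds) + 1L -
               findInterval(egfr, rev(thresholds), left.open = FALSE))
}

#' Prevalence of CKD at or above a cut-off stage
#'
#' @param panel an [egfr_panel()].
#' @param equation panel column to stage on.
#' @param cutoff_stage stage k; subjects with stage >= k are counted.
#' @param thresholds see [ckd_stage()].
#' @return tibble: `equation`, `cutoff_stage`, `n`, `count`, `percent`.
#' @export
stage_prevalence <- function(panel, equation, cutoff_stage = 3,
                             thresholds = stage_thresholds()) {
  stopifnot(cutoff_stage %in% 2:5)
  st <- ckd_stage(panel[[equation]], thresholds)
  tibble::tibble(equation = equation, cutoff_stage = cutoff_stage,
                 n = length(st), count = sum(st >= cutoff_stage),
                 percent = 100 * mean(st >= cutoff_stage))
}

#' Stage cross-classification and dichotomized discrepancy for two formulae
#'
#' Cross-tabulates CKD stages under methods A and B, and dichotomizes at the
#' cut-off stage k: subjects staged >= k by both or < k by both are
#' concordant; `a_not_b` are staged >= k only by A, `b_not_a` only by B.
#' Percentages are against the total n.
#'
#' @param panel an [egfr_panel()].
#' @param eq_a,eq_b panel columns for methods A (first-named) and B.
#' @param cutoff_stage dichotomization stage (2 or 3 in the standard report).
#' @param thresholds see [ckd_stage()].
#' @return an object of class `stage_crosstab`: a list with `crosstab`
#'   (5 x 5 count matrix, A rows x B columns), `summary` (one-row tibble with
#'   `concordant`, `a_not_b`, `b_not_a` counts and `_pct` columns), `n`,
#'   `cutoff_stage` and the pair labels.
#' @export
stage_crosstab <- function(panel, eq_a, eq_b, cutoff_stage = 3,
                           thresholds = stage_thresholds()) {
  sa <- ckd_stage(panel[[eq_a]], thresholds)
  sb <- ckd_stage(panel[[eq_b]], thresholds)
  n <- length(sa)
  tab <- table(factor(sa, levels = 1:5), factor(sb, levels = 1:5))
  dimnames(tab) <- list(a_stage = 1:5, b_stage = 1:5)
  ge_a <- sa >= cutoff_stage
  ge_b <- sb >= cutoff_stage
  concordant <- sum(ge_a == ge_b)
  a_not_b <- sum(ge_a & !ge_b)
  b_not_a <- sum(!ge_a & ge_b)
  summary <- tibble::tibble(
    eq_a = eq_a, eq_b = eq_b, cutoff_stage = cutoff_stage, n = n,
    concordant = concordant, concordant_pct = 100 * concordant / n,
    a_not_b = a_not_b, a_not_b_pct = 100 * a_not_b / n,
    b_not_a = b_not_a, b_not_a_pct = 100 * b_not_a / n)
  structure(list(crosstab = unclass(tab), summary = summary, n = n,
                 cutoff_stage = cutoff_stage, eq_a = eq_a, eq_b = eq_b),
            class = "stage_crosstab")
}

#' @export
print.stage_crosstab <- function(x, ...) {
  cat("CKD stage cross-classification: ", x$eq_a, " (A) vs ", x$eq_b,
      " (B), cut-off stage ", x$cutoff_stage, "\n\n", sep = "")
  print(x$crosstab)
  cat("\n")
  print(x$summary[, c("concordant", "a_not_b", "b_not_a")])
  invisible(x)
}

#' Staging discrepancy table for a set of formula pairs
#'
#' One row per (pair, cut-off stage), in the layout of the standard
#' discrepancy report.
#'
#' @param panel an [egfr_panel()].
#' @param comparisons tibble with columns `reference` (A) and `predictor` (B).
#' @param cutoff_stages stages at which to dichotomize (default `c(2, 3)`).
#' @param thresholds see [ckd_stage()].
#' @return tibble binding the `summary` rows of [stage_crosstab()].
#' @export
staging_table <- function(panel, comparisons = default_comparisons(),
                          cutoff_stages = c(2, 3),
                          thresholds = stage_thresholds()) {
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    dplyr::bind_rows(lapply(sort(cutoff_stages), function(k) {
      stage_crosstab(panel, comparisons$reference[i], comparisons$predictor[i],
                     cutoff_stage = k, thresholds = thresholds)$summary
    }))
  })
  dplyr::bind_rows(rows)
}
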