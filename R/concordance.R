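# Numeric concordance summaries for an ordered formula pair: absolute bias,
# precision (SE of the mean difference), relative bias, and P10/P30 accuracy.
# All honour the reference-first ordering of pair_estimates(): d = a - b,
# negative bias means B overestimates the reference A.

strata_splits <- function(pe, include_overall = TRUE) {
  splits <- split(pe, pe$stratum)
  if (include_overall && length(splits) > 1) {
    splits <- c(list(overall = pe), splits)
  } else if (include_overall && length(splits) == 1) {
    names(splits) <- "overall"
  }
  splits
}

#' Absolute bias (mean difference) per stratum
#'
#' Mean of `d = a - b`. Negative values mean the predictor B overestimates
#' the reference A.
#'
#' @param pe a [pair_estimates()] result.
#' @param include_overall prepend a pooled `"overall"` row (default TRUE).
#' @return tibble: `stratum`, `n`, `absolute_bias`.
#' @export
absolute_bias <- function(pe, include_overall = TRUE) {
  dplyr::bind_rows(lapply(names(ss <- strata_splits(pe, include_overall)),
    function(nm) {
      s <- ss[[nm]]
      if (nrow(s) == 0) {
        warning("empty stratum '", nm, "' omitted", call. = FALSE)
        return(NULL)
      }
      tibble::tibble(stratum = nm, n = nrow(s), absolute_bias = mean(s$d))
    }))
}

#' Precision: standard error of the mean difference
#'
#' `sd(d) / sqrt(n)` with the sample (n-1) standard deviation. Smaller values
#' indicate less variable disagreement between the two methods.
#'
#' @inheritParams absolute_bias
#' @return tibble: `stratum`, `n`, `precision`.
#' @export
precision_se <- function(pe, include_overall = TRUE) {
  dplyr::bind_rows(lapply(names(ss <- strata_splits(pe, include_overall)),
    function(nm) {
      s <- ss[[nm]]
      if (nrow(s) < 2) {
        stop("precision needs >= 2 pairs in stratum '", nm, "'", call. = FALSE)
      }
      tibble::tibble(stratum = nm, n = nrow(s),
                     precision = sd(s$d) / sqrt(nrow(s)))
    }))
}

#' Relative bias in percent
#'
#' Default (`method = "mean_ratio"`): `100 * (mean(b) - mean(a)) / mean(a)`,
#' the mean difference scaled by the reference mean and sign-flipped relative
#' to [absolute_bias()], so a predictor that overestimates the reference has
#' negative absolute bias and positive relative bias.
#' `method = "per_subject"` averages `100 * (b - a) / a` instead (sensitivity
#' alternative).
#'
#' @inheritParams absolute_bias
#' @param method `"mean_ratio"` (default) or `"per_subject"`.
#' @return tibble: `stratum`, `n`, `relative_bias_pct`.
#' @export
relative_bias <- function(pe, method = c("mean_ratio", "per_subject"),
                          include_overall = TRUE) {
  method <- match.arg(method)
  dplyr::bind_rows(lapply(names(ss <- strata_splits(pe, include_overall)),
    function(nm) {
      s <- ss[[nm]]
      if (nrow(s) == 0) {
        warning("empty stratum '", nm, "' omitted", call. = FALSE)
        return(NULL)
      }
      if (mean(s$a) <= 0) {
        stop("reference mean must be positive in stratum '", nm, "'",
             call. = FALSE)
      }
      val <- switch(method,
                    mean_ratio = 100 * (mean(s$b) - mean(s$a)) / mean(s$a),
                    per_subject = mean(100 * (s$b - s$a) / s$a))
      tibble::tibble(stratum = nm, n = nrow(s), relative_bias_pct = val)
    }))
}

#' Accuracy within a relative margin (P10/P30)
#'
#' Percentage of subjects whose reference value a lies within
#' `margin * b` of the predictor value b, i.e. `|a - b| <= margin * b`
#' (boundary inclusive). `margin = 0.30` gives the familiar P30.
#'
#' @inheritParams absolute_bias
#' @param margin relative margin as a fraction in (0, 1).
#' @return tibble: `stratum`, `n`, `margin`, `accuracy_pct`.
#' @export
accuracy_within <- function(pe, margin, include_overall = TRUE) {
  stopifnot(is.numeric(margin), length(margin) == 1, margin > 0, margin < 1)
  if (any(pe$b <= 0)) {
    stop("accuracy margins are relative to method B; all b must be > 0",
         call. = FALSE)
  }
  dplyr::bind_rows(lapply(names(ss <- strata_splits(pe, include_overall)),
    function(nm) {
      s <- ss[[nm]]
      tibble::tibble(stratum = nm, n = nrow(s), margin = margin,
                     accuracy_pct = 100 * mean(abs(s$a - s$b) <= margin * s$b))
    }))
}

#' Default comparison pairs
#'
#' The ten ordered (reference, predictor) pairs of the standard report: each
#' creatinine equation (with and without the black-American factor) against the
#' van Deventer cystatin C reference, the simple CKD-EPI cystatin C equation
#' against CKD-EPI creatinine (both variants), and the creatinine equations
#' against each other.
#'
#' @return tibble with columns `reference`, `predictor`.
#' @export
default_comparisons <- function() {
  tibble::tribble(
    ~reference,            ~predictor,
    "van_deventer",        "ckd_epi_cr",
    "van_deventer",        "mdrd4",
    "van_deventer",        "cockcroft_gault",
    "van_deventer",        "ckd_epi_cr_black",
    "van_deventer",        "mdrd4_black",
    "ckd_epi_cysc_simple", "ckd_epi_cr_black",
    "ckd_epi_cysc_simple", "ckd_epi_cr",
    "cockcroft_gault",     "mdrd4",
    "cockcroft_gault",     "ckd_epi_cr",
    "mdrd4",               "ckd_epi_cr"
  )
}

#' Concordance table for a set of formula pairs
#'
#' One row per (pair, stratum): n, absolute bias, precision, relative bias and
#' accuracy at the requested margins. Strata are `overall` plus the levels of
#' `stratify_by` (when present), in a deterministic order.
#'
#' @param panel an [egfr_panel()] containing every referenced equation.
#' @param comparisons tibble with columns `reference`, `predictor`
#'   (default [default_comparisons()]).
#' @param stratify_by stratification column of `panel`, or `NULL`.
#' @param margins accuracy margins (fractions), default `c(0.10, 0.30)`.
#' @return tibble: `reference`, `predictor`, `stratum`, `n`, `absolute_bias`,
#'   `precision`, `relative_bias_pct`, then one `p<k>_pct` column per margin.
#' @export
concordance_table <- function(panel, comparisons = default_comparisons(),
                              stratify_by = "hiv_status",
                              margins = c(0.10, 0.30)) {
  if (!is.null(stratify_by) && !stratify_by %in% names(panel)) {
    stratify_by <- NULL
  }
  missing_eq <- setdiff(unique(c(comparisons$reference, comparisons$predictor)),
                        names(panel))
  if (length(missing_eq) > 0) {
    stop("panel lacks equation column(s): ",
         paste(missing_eq, collapse = ", "), call. = FALSE)
  }
  rows <- lapply(seq_len(nrow(comparisons)), function(i) {
    ref <- comparisons$reference[i]
    prd <- comparisons$predictor[i]
    pe <- pair_estimates(panel, ref, prd, stratify_by = stratify_by)
    res <- dplyr::full_join(absolute_bias(pe), precision_se(pe),
                            by = c("stratum", "n"))
    res <- dplyr::full_join(res, relative_bias(pe), by = c("stratum", "n"))
    for (mg in sort(margins)) {
      acc <- accuracy_within(pe, mg)
      col <- paste0("p", round(100 * mg), "_pct")
      res[[col]] <- acc$accuracy_pct[match(res$stratum, acc$stratum)]
    }
    tibble::add_column(res, reference = ref, predictor = prd, .before = 1)
  })
  dplyr::bind_rows(rows)
}
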