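# GFR estimating equations.
#
# All equations return mL/min/1.73 m2 except Cockcroft-Gault, which estimates
# creatinine clearance in raw mL/min (no body-surface-area indexing); downstream
# summaries carry a unit flag so the mismatch is never silent.

#' Normalise a sex vector to "female"/"male"
#'
#' Accepts common encodings ("female"/"male", "f"/"m", case-insensitive,
#' 0/1 is *not* accepted because the mapping is ambiguous).
#'
#' @param sex character vector.
#' @return character vector of `"female"`/`"male"`; `NA` preserved.
#' @keywords internal
normalize_sex <- function(sex) {
  s <- tolower(trimws(as.character(sex)))
  out <- rep(NA_character_, length(s))
  out[s %in% c("female", "f", "w", "woman", "women")] <- "female"
  out[s %in% c("male", "m", "man", "men")] <- "male"
  bad <- !is.na(s) & s != "" & is.na(out)
  if (any(bad)) {
    stop("unrecognised sex value(s): ",
         paste(unique(s[bad]), collapse = ", "),
         "; expected 'female' or 'male'", call. = FALSE)
  }
  out
}

assert_positive <- function(x, what, equation) {
  bad <- !is.na(x) & (!is.finite(x) | x <= 0)
  if (any(bad)) {
    stop(sprintf("%s requires %s > 0 (got %s)", equation, what,
                 paste(head(unique(x[bad]), 3), collapse = ", ")),
         call. = FALSE)
  }
  invisible(x)
}

#' Cockcroft-Gault creatinine clearance
#'
#' `(140 - age) * weight * 0.85[if female] / (72 * SCr)`. The result is a
#' creatinine clearance in mL/min, *not* indexed to 1.73 m2 body surface area;
#' it carries attribute `units = "mL/min"` so panel summaries can flag it.
#'
#' @param age age in years (adults; must be < 140).
#' @param weight body weight in kg (required).
#' @param sex `"female"` or `"male"` (common encodings accepted).
#' @param scr serum creatinine in mg/dL.
#' @return numeric vector, mL/min.
#' @examples
#' egfr_cockcroft_gault(40, 72, "male", 1.0)   # 100
#' egfr_cockcroft_gault(40, 72, "female", 1.0) # 85
#' @export
egfr_cockcroft_gault <- function(age, weight, sex, scr) {
  if (missing(weight) || all(is.na(weight))) {
    stop("Cockcroft-Gault requires body weight (kg); none supplied",
         call. = FALSE)
  }
  if (any(is.na(weight) & !is.na(scr))) {
    stop("Cockcroft-Gault requires body weight (kg); missing for some subjects",
         call. = FALSE)
  }
  sex <- normalize_sex(sex)
  assert_positive(scr, "serum creatinine (mg/dL)", "Cockcroft-Gault")
  assert_positive(weight, "weight (kg)", "Cockcroft-Gault")
  if (any(!is.na(age) & age >= 140)) {
    stop("Cockcroft-Gault is undefined for age >= 140 years", call. = FALSE)
  }
  out <- (140 - age) * weight * ifelse(sex == "female", 0.85, 1) / (72 * scr)
  attr(out, "units") <- "mL/min"
  out
}

#' MDRD-4 (IDMS-traceable) eGFR
#'
#' `175 * SCr^-1.154 * age^-0.203 * 1.212[if black] * 0.742[if female]`,
#' in mL/min/1.73 m2.
#'
#' @inheritParams egfr_cockcroft_gault
#' @param black_factor apply the multiplicative 1.212 factor derived in US
#'   cohorts for self-identified black Americans. An analysis switch, not a
#'   per-subject field: the cohorts this package targets are ethnically
#'   homogeneous and the question is whether the factor applies at all.
#' @return numeric vector, mL/min/1.73 m2.
#' @export
egfr_mdrd4 <- function(scr, age, sex, black_factor = FALSE) {
  sex <- normalize_sex(sex)
  assert_positive(scr, "serum creatinine (mg/dL)", "MDRD-4")
  assert_positive(age, "age (years)", "MDRD-4")
  175 * scr^-1.154 * age^-0.203 *
    (if (isTRUE(black_factor)) 1.212 else 1) *
    ifelse(sex == "female", 0.742, 1)
}

#' CKD-EPI 2009 creatinine eGFR
#'
#' Piecewise power law in SCr with a sex-specific knot (0.7 mg/dL female,
#' 0.9 mg/dL male), sex-specific low-range exponent (-0.329 / -0.411), shared
#' high-range exponent -1.209, and age decay 0.993^age. Coefficients 144/141
#' (female/male) or, with the black-American factor, 166/163.
#'
#' @inheritParams egfr_mdrd4
#' @return numeric vector, mL/min/1.73 m2.
#' @export
egfr_ckd_epi_cr <- function(scr, age, sex, black_factor = FALSE) {
  sex <- normalize_sex(sex)
  assert_positive(scr, "serum creatinine (mg/dL)", "CKD-EPI (creatinine)")
  assert_positive(age, "age (years)", "CKD-EPI (creatinine)")
  female <- sex == "female"
  kappa <- ifelse(female, 0.7, 0.9)
  alpha <- ifelse(female, -0.329, -0.411)
  coefb <- if (isTRUE(black_factor)) c(166, 163) else c(144, 141)
  coef0 <- ifelse(female, coefb[1], coefb[2])
  expo <- ifelse(scr <= kappa, alpha, -1.209)
  coef0 * (scr / kappa)^expo * 0.993^age
}

#' Van Deventer cystatin C eGFR
#'
#' `10^(2.35 - 0.33 * SCysC - 0.003 * age)`, mL/min/1.73 m2; derived in a
#' South African cohort, which makes it the natural cystatin C reference for
#' sub-Saharan populations.
#'
#' @param scysc serum cystatin C in mg/L.
#' @param age age in years.
#' @return numeric vector, mL/min/1.73 m2.
#' @export
egfr_van_deventer <- function(scysc, age) {
  assert_positive(scysc, "serum cystatin C (mg/L)", "van Deventer")
  assert_positive(age, "age (years)", "van Deventer")
  10^(2.35 - 0.33 * scysc - 0.003 * age)
}

#' CKD-EPI cystatin C eGFR
#'
#' Two variants: `"simple"` is `76.7 * SCysC^-1.19` (no demographic terms);
#' `"full"` is `127.7 * SCysC^-1.17 * age^-0.13 * 0.91[if female] *
#' 1.06[if black]`.
#'
#' @inheritParams egfr_van_deventer
#' @param sex required for `variant = "full"`.
#' @param variant `"simple"` or `"full"`.
#' @param black_factor 1.06 multiplier; only meaningful (and only accepted)
#'   for `variant = "full"`.
#' @return numeric vector, mL/min/1.73 m2.
#' @export
egfr_ckd_epi_cysc <- function(scysc, age = NULL, sex = NULL,
                              variant = c("simple", "full"),
                              black_factor = FALSE) {
  variant <- match.arg(variant)
  assert_positive(scysc, "serum cystatin C (mg/L)", "CKD-EPI (cystatin C)")
  if (variant == "simple") {
    if (isTRUE(black_factor)) {
      stop("the simple CKD-EPI cystatin C equation has no black-American ",
           "factor; black_factor = TRUE is not allowed", call. = FALSE)
    }
    return(76.7 * scysc^-1.19)
  }
  if (is.null(age) || is.null(sex)) {
    stop("CKD-EPI cystatin C (full) requires age and sex", call. = FALSE)
  }
  sex <- normalize_sex(sex)
  assert_positive(age, "age (years)", "CKD-EPI (cystatin C, full)")
  127.7 * scysc^-1.17 * age^-0.13 *
    ifelse(sex == "female", 0.91, 1) *
    (if (isTRUE(black_factor)) 1.06 else 1)
}

#' Registry of equation variants
#'
#' One row per evaluable variant. `equation` is the panel column name; `base`
#' names the underlying formula; `black_factor` marks the 1.212 / 166-163 /
#' 1.06 variants. Only MDRD-4, CKD-EPI creatinine and CKD-EPI cystatin C
#' (full) have such a factor.
#'
#' @param black `"both"` (default: factor and no-factor variants),
#'   `"none"`, or `"only"`.
#' @return a tibble with columns `equation`, `base`, `black_factor`,
#'   `biomarker`, `units`, `label`.
#' @export
egfr_equations <- function(black = c("both", "none", "only")) {
  black <- match.arg(black)
  reg <- tibble::tribble(
    ~equation,                  ~base,                 ~black_factor, ~biomarker,   ~units,               ~label,
    "cockcroft_gault",          "cockcroft_gault",     FALSE,         "creatinine", "mL/min",             "Cockcroft-Gault",
    "mdrd4",                    "mdrd4",               FALSE,         "creatinine", "mL/min/1.73m2",      "MDRD-4",
    "mdrd4_black",              "mdrd4",               TRUE,          "creatinine", "mL/min/1.73m2",      "MDRD-4 (black factor)",
    "ckd_epi_cr",               "ckd_epi_cr",          FALSE,         "creatinine", "mL/min/1.73m2",      "CKD-EPI",
    "ckd_epi_cr_black",         "ckd_epi_cr",          TRUE,          "creatinine", "mL/min/1.73m2",      "CKD-EPI (black factor)",
    "van_deventer",             "van_deventer",        FALSE,         "cystatin_c", "mL/min/1.73m2",      "Cystatin C (van Deventer)",
    "ckd_epi_cysc_simple",      "ckd_epi_cysc_simple", FALSE,         "cystatin_c", "mL/min/1.73m2",      "CKD-EPI cystatin C (simple)",
    "ckd_epi_cysc_full",        "ckd_epi_cysc_full",   FALSE,         "cystatin_c", "mL/min/1.73m2",      "CKD-EPI cystatin C (full)",
    "ckd_epi_cysc_full_black",  "ckd_epi_cysc_full",   TRUE,          "cystatin_c", "mL/min/1.73m2",      "CKD-EPI cystatin C (full, black factor)"
  )
  switch(black,
         both = reg,
         none = reg[!reg$black_factor, ],
         only = reg[reg$black_factor, ])
}

#' Evaluate one equation variant on a cohort
#'
#' @param cohort a data frame with the columns the variant needs (`age`, `sex`,
#'   `scr`, `scysc`, `weight`).
#' @param equation a variant id from [egfr_equations()] (e.g. `"ckd_epi_cr"`,
#'   `"mdrd4_black"`).
#' @return numeric vector of eGFR values, one per row of `cohort`.
#' @export
egfr <- function(cohort, equation) {
  reg <- egfr_equations()
  if (!equation %in% reg$equation) {
    stop("unknown equation '", equation, "'; see egfr_equations()",
         call. = FALSE)
  }
  row <- reg[reg$equation == equation, ]
  need <- function(col) {
    if (!col %in% names(cohort)) {
      stop("equation '", equation, "' needs column '", col, "'", call. = FALSE)
    }
    cohort[[col]]
  }
  switch(row$base,
    cockcroft_gault = egfr_cockcroft_gault(need("age"), need("weight"),
                                           need("sex"), need("scr")),
    mdrd4 = egfr_mdrd4(need("scr"), need("age"), need("sex"),
                       black_factor = row$black_factor),
    ckd_epi_cr = egfr_ckd_epi_cr(need("scr"), need("age"), need("sex"),
                                 black_factor = row$black_factor),
    van_deventer = egfr_van_deventer(need("scysc"), need("age")),
    ckd_epi_cysc_simple = egfr_ckd_epi_cysc(need("scysc"), variant = "simple"),
    ckd_epi_cysc_full = egfr_ckd_epi_cysc(need("scysc"), need("age"),
                                          need("sex"), variant = "full",
                                          black_factor = row$black_factor)
  )
}

#' Evaluate a panel of equations on a cohort
#'
#' Runs every requested variant on every subject and returns one column per
#' variant next to the subject id (and any carried descriptive columns, by
#' default `hiv_status` when present, so stratified comparisons need no join).
#'
#' @param cohort data frame of subject records.
#' @param equations character vector of variant ids (default: all nine).
#' @param carry columns of `cohort` copied into the result when present.
#' @return a tibble of class `egfr_panel`; attribute `units` maps each variant
#'   to its unit string (Cockcroft-Gault is mL/min, unindexed).
#' @examples
#' cohort <- tibble::tibble(id = "a", age = 31, sex = "male", weight = 65,
#'                          scr = 0.73, scysc = 0.78)
#' egfr_panel(cohort, c("ckd_epi_cr", "van_deventer"))
#' @export
egfr_panel <- function(cohort, equations = egfr_equations()$equation,
                       carry = "hiv_status") {
  reg <- egfr_equations()
  unknown <- setdiff(equations, reg$equation)
  if (length(unknown) > 0) {
    stop("unknown equation id(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  if (!"id" %in% names(cohort)) {
    cohort$id <- as.character(seq_len(nrow(cohort)))
  }
  out <- tibble::tibble(id = as.character(cohort$id))
  for (col in intersect(carry, names(cohort))) out[[col]] <- cohort[[col]]
  for (eq in equations) {
    val <- tryCatch(as.numeric(egfr(cohort, eq)), error = function(e) {
      stop("equation '", eq, "' failed: ", conditionMessage(e), call. = FALSE)
    })
    bad <- !is.na(val) & (!is.finite(val) | val <= 0)
    if (any(bad)) {
      stop("equation '", eq, "' produced non-positive or non-finite values ",
           "for subject(s) ", paste(head(out$id[bad], 5), collapse = ", "),
           call. = FALSE)
    }
    out[[eq]] <- val
  }
  units <- setNames(reg$units[match(equations, reg$equation)], equations)
  structure(out, units = units,
            class = c("egfr_panel", class(out)))
}
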