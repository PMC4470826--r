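# Synthetic cohort generator.
#
# Emulates the marginal structure of a Malawian adult HIV-testing-centre
# cohort: HIV prevalence 32%, 48% female, median age 31 (IQR 26-39), and
# HIV-stratum-specific body-mass index, serum creatinine and cystatin C, each
# log-normal calibrated from the published median/IQR. Log-creatinine and
# log-cystatin-C are linked by a Gaussian copula with configurable
# correlation. A small "CKD spike" component multiplies both biomarkers so
# stages 3-5 are occupied, which the real cohort barely was.

#' Solve log-normal parameters from a median and IQR
#'
#' `mu = log(median)`; `sigma = log(q3/q1) / (2 * z_0.75)` with
#' `z_0.75 = qnorm(0.75) = 0.6744898`. Exact when the data are log-normal, in
#' which case the implied quartiles round-trip.
#'
#' @param median,q1,q3 summary statistics with `0 < q1 < median < q3`.
#' @return named numeric vector `c(mu, sigma)` (log-scale mean and SD).
#' @examples
#' solve_lognormal(0.74, 0.64, 0.85)  # sigma ~ 0.2104
#' @export
solve_lognormal <- function(median, q1, q3) {
  if (!(is.finite(median) && is.finite(q1) && is.finite(q3) &&
        q1 > 0 && q1 < median && median < q3)) {
    stop("need 0 < q1 < median < q3 (got q1=", q1, ", median=", median,
         ", q3=", q3, ")", call. = FALSE)
  }
  c(mu = log(median), sigma = log(q3 / q1) / (2 * qnorm(0.75)))
}

mqq <- function(median, q1, q3) list(median = median, q1 = q1, q3 = q3)

#' Parameters of the synthetic cohort
#'
#' Defaults reproduce the marginal summaries of the Malawian study cohort:
#' n = 363, 32% HIV-positive, 48% female; age median 31 (IQR 26-39),
#' truncated at 18; per-HIV-stratum medians (IQRs): BMI 20.8 (19.0-22.9)
#' positive vs 22.6 (20.9-26.2) negative; creatinine 0.69 (0.59-0.83) vs
#' 0.74 (0.64-0.85) mg/dL; cystatin C 0.87 (0.78-0.98) vs 0.75 (0.67-0.84)
#' mg/L. The creatinine-cystatin C log-scale correlation (0.5) and the CKD
#' spike (3% of subjects, both biomarkers x 2.5) are free parameters the
#' study did not report.
#'
#' @param n cohort size.
#' @param hiv_prevalence,female_fraction fractions in \[0, 1\].
#' @param age list `(median, q1, q3)` in years plus truncation handled at 18.
#' @param bmi,scr,scysc lists with elements `positive` and `negative`, each a
#'   `(median, q1, q3)` list (kg/m2, mg/dL, mg/L).
#' @param scr_scysc_correlation Gaussian-copula correlation of log-SCr and
#'   log-SCysC within stratum, `|rho| < 1`.
#' @param ckd_fraction fraction of subjects drawn from the elevated-biomarker
#'   component.
#' @param ckd_severity multiplier applied to both biomarkers of spike
#'   subjects.
#' @param height sex-specific normal height parameters in metres (feeds
#'   weight = BMI * height^2, used only by Cockcroft-Gault).
#' @param seed integer RNG seed recorded in the parameters (can be overridden
#'   in [generate_cohort()]).
#' @return a validated list of class `cohort_params`.
#' @export
cohort_params <- function(n = 363,
                          hiv_prevalence = 0.32,
                          female_fraction = 0.48,
                          age = mqq(31, 26, 39),
                          bmi = list(positive = mqq(20.8, 19.0, 22.9),
                                     negative = mqq(22.6, 20.9, 26.2)),
                          scr = list(positive = mqq(0.69, 0.59, 0.83),
                                     negative = mqq(0.74, 0.64, 0.85)),
                          scysc = list(positive = mqq(0.87, 0.78, 0.98),
                                       negative = mqq(0.75, 0.67, 0.84)),
                          scr_scysc_correlation = 0.5,
                          ckd_fraction = 0.03,
                          ckd_severity = 2.5,
                          height = list(female = c(mean = 1.57, sd = 0.06),
                                        male = c(mean = 1.68, sd = 0.07)),
                          seed = 1L) {
  stopifnot(n >= 1,
            hiv_prevalence >= 0, hiv_prevalence <= 1,
            female_fraction >= 0, female_fraction <= 1,
            abs(scr_scysc_correlation) < 1,
            ckd_fraction >= 0, ckd_fraction <= 1,
            ckd_severity > 0)
  # every median/IQR triple must be solvable (errors early, before any draw)
  solve_lognormal(age$median, age$q1, age$q3)
  for (v in list(bmi, scr, scysc)) {
    for (s in c("positive", "negative")) {
      solve_lognormal(v[[s]]$median, v[[s]]$q1, v[[s]]$q3)
    }
  }
  # keep as named lists so the parameters survive JSON serialization intact
  height <- lapply(height, as.list)
  stopifnot(height$female$sd > 0, height$male$sd > 0)
  structure(list(n = as.integer(n), hiv_prevalence = hiv_prevalence,
                 female_fraction = female_fraction, age = age, bmi = bmi,
                 scr = scr, scysc = scysc,
                 scr_scysc_correlation = scr_scysc_correlation,
                 ckd_fraction = ckd_fraction, ckd_severity = ckd_severity,
                 height = height, seed = as.integer(seed)),
            class = "cohort_params")
}

#' Generate a synthetic cohort
#'
#' Draws a cohort from the model described in [cohort_params()]: HIV status
#' and sex are Bernoulli; age is log-normal truncated below 18 (inverse-CDF
#' truncation, no rejection); within each HIV stratum (log SCr, log SCysC)
#' are jointly Gaussian with the configured correlation; BMI is log-normal per
#' stratum; height is normal per sex and weight = BMI * height^2; finally a
#' `ckd_fraction` of subjects have both biomarkers multiplied by
#' `ckd_severity` (flagged in column `ckd_component`).
#'
#' Deterministic: the same parameters and seed give a byte-identical cohort.
#'
#' @param params a [cohort_params()] object.
#' @param seed overrides `params$seed` when given.
#' @return a tibble of class `egfr_cohort` with columns `id`, `age`, `sex`,
#'   `hiv_status`, `height`, `weight`, `bmi`, `scr`, `scysc`,
#'   `ckd_component`.
#' @examples
#' cohort <- generate_cohort(cohort_params(n = 100), seed = 7)
#' median(cohort$scr)
#' @export
generate_cohort <- function(params = cohort_params(), seed = NULL) {
  if (!inherits(params, "cohort_params")) {
    stop("params must come from cohort_params()", call. = FALSE)
  }
  seed <- if (is.null(seed)) params$seed else as.integer(seed)
  withr::with_seed(seed, {
    n <- params$n
    hiv <- ifelse(runif(n) < params$hiv_prevalence, "positive", "negative")
    sex <- ifelse(runif(n) < params$female_fraction, "female", "male")

    ap <- solve_lognormal(params$age$median, params$age$q1, params$age$q3)
    p18 <- plnorm(18, ap["mu"], ap["sigma"])
    age <- qlnorm(p18 + runif(n) * (1 - p18), ap["mu"], ap["sigma"])

    rho <- params$scr_scysc_correlation
    z1 <- rnorm(n)
    z2 <- rho * z1 + sqrt(1 - rho^2) * rnorm(n)
    zb <- rnorm(n)

    scr <- scysc <- bmi <- numeric(n)
    for (s in c("positive", "negative")) {
      idx <- hiv == s
      pc <- solve_lognormal(params$scr[[s]]$median, params$scr[[s]]$q1,
                            params$scr[[s]]$q3)
      py <- solve_lognormal(params$scysc[[s]]$median, params$scysc[[s]]$q1,
                            params$scysc[[s]]$q3)
      pb <- solve_lognormal(params$bmi[[s]]$median, params$bmi[[s]]$q1,
                            params$bmi[[s]]$q3)
      scr[idx] <- exp(pc["mu"] + pc["sigma"] * z1[idx])
      scysc[idx] <- exp(py["mu"] + py["sigma"] * z2[idx])
      bmi[idx] <- exp(pb["mu"] + pb["sigma"] * zb[idx])
    }

    hf <- params$height$female
    hm <- params$height$male
    height <- ifelse(sex == "female",
                     rnorm(n, hf$mean, hf$sd),
                     rnorm(n, hm$mean, hm$sd))
    height <- pmax(height, 1.2)  # guard against absurd draws in the far tail

    spike <- runif(n) < params$ckd_fraction
    scr[spike] <- scr[spike] * params$ckd_severity
    scysc[spike] <- scysc[spike] * params$ckd_severity

    cohort <- tibble::tibble(
      id = sprintf("S%04d", seq_len(n)),
      age = age, sex = sex, hiv_status = hiv,
      height = height, weight = bmi * height^2, bmi = bmi,
      scr = scr, scysc = scysc, ckd_component = spike)
    structure(cohort,
              provenance = list(file = NA_character_, format = "simulated",
                                seed = seed, params = params),
              exclusions = tibble::tibble(row = integer(), id = character(),
                                          reason = character()),
              class = unique(c("egfr_cohort", class(cohort))))
  })
}
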