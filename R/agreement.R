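# Bland-Altman agreement between two eGFR methods.
#
# Differences d = a - b are plotted against pairwise means m = (a + b)/2.
# Sign convention: method A is the first-named reference, so d < 0 means the
# predictor B overestimates the reference. Limits of agreement use the
# "two standard deviations" band; for heteroscedastic data the mean difference
# and the SD are both modelled as linear functions of m (Bland & Altman 1999:
# regress |residuals| on m, E|r| = sigma * sqrt(2/pi)).

#' Paired estimates for two equations
#'
#' Builds the per-subject pairs (a, b, m, d) for a Bland-Altman comparison.
#' A is the first-named method and acts as the reference throughout; the
#' difference is `d = a - b` and the abscissa is `m = (a + b) / 2`.
#'
#' @param panel an [egfr_panel()] (or any data frame holding both columns).
#' @param eq_a,eq_b column names of the reference (A) and predictor (B).
#' @param stratify_by optional column of `panel` defining strata (typically
#'   `"hiv_status"`). `NULL` puts everyone in stratum `"all"`.
#' @return tibble of class `paired_estimates` with columns `id`, `stratum`,
#'   `a`, `b`, `m`, `d`; subjects with a missing value in either method are
#'   dropped and counted in attribute `n_excluded`.
#' @examples
#' pe <- pair_estimates(
#'   tibble::tibble(id = 1:2, x = c(100, 90), y = c(80, 90)), "x", "y")
#' pe$d  # 20, 0
#' @export
pair_estimates <- function(panel, eq_a, eq_b, stratify_by = NULL) {
  for (eq in c(eq_a, eq_b)) {
    if (!eq %in% names(panel)) {
      stop("column '", eq, "' not found in panel", call. = FALSE)
    }
  }
  if (identical(eq_a, eq_b)) {
    # allowed (gives d == 0); the caller may use it as a null comparison
  }
  id <- if ("id" %in% names(panel)) as.character(panel$id) else
    as.character(seq_len(nrow(panel)))
  stratum <- if (is.null(stratify_by)) {
    rep("all", nrow(panel))
  } else {
    if (!stratify_by %in% names(panel)) {
      stop("stratification column '", stratify_by, "' not found in panel",
           call. = FALSE)
    }
    as.character(panel[[stratify_by]])
  }
  a <- as.numeric(panel[[eq_a]])
  b <- as.numeric(panel[[eq_b]])
  keep <- is.finite(a) & is.finite(b) & !is.na(stratum)
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " subject(s) excluded from pairing (missing values)")
  }
  out <- tibble::tibble(id = id[keep], stratum = stratum[keep],
                        a = a[keep], b = b[keep],
                        m = (a[keep] + b[keep]) / 2,
                        d = a[keep] - b[keep])
  structure(out, eq_a = eq_a, eq_b = eq_b, n_excluded = n_excluded,
            class = c("paired_estimates", class(out)))
}

# evaluation grid over the observed m range of one stratum
loa_grid <- function(m, grid_n) {
  r <- range(m)
  if (r[1] == r[2]) r <- r + c(-0.5, 0.5)
  seq(r[1], r[2], length.out = grid_n)
}

curve_tibble <- function(stratum, m, mean_diff, lower, upper, method, n) {
  tibble::tibble(stratum = stratum, m = m, mean_diff = mean_diff,
                 lower = lower, upper = upper, method = method, n = n)
}

#' Classic Bland-Altman limits of agreement
#'
#' Constant lines: mean difference, and mean plus/minus `multiplier` sample
#' standard deviations of the differences. Computed independently per stratum.
#'
#' @param pe a [pair_estimates()] result.
#' @param multiplier half-width of the band in SD units; 2 by default
#'   ("two standard deviations"); 1.96 gives exact normal 95% limits.
#' @param grid_n number of grid points per stratum on which the (constant)
#'   lines are evaluated, for a uniform plot-data contract across methods.
#' @return tibble of class `agreement_curve`: `stratum`, `m`, `mean_diff`,
#'   `lower`, `upper`, `method`, `n`.
#' @export
ba_classic <- function(pe, multiplier = 2, grid_n = 100) {
  out <- lapply(split(pe, pe$stratum), function(s) {
    if (nrow(s) < 3) {
      stop("classic limits of agreement need >= 3 pairs in stratum '",
           s$stratum[1], "' (got ", nrow(s), ")", call. = FALSE)
    }
    g <- loa_grid(s$m, grid_n)
    mu <- mean(s$d)
    sdd <- sd(s$d)
    curve_tibble(s$stratum[1], g, rep(mu, grid_n),
                 rep(mu - multiplier * sdd, grid_n),
                 rep(mu + multiplier * sdd, grid_n),
                 "classic", nrow(s))
  })
  as_agreement_curve(dplyr::bind_rows(out), pe)
}

#' Regression-based limits of agreement under heteroscedasticity
#'
#' The mean difference is modelled as a least-squares line `d ~ m`; the
#' residual scale as a line in m, estimated by regressing the absolute
#' residuals on m and rescaling by `sqrt(pi/2)` (for a normal residual,
#' `E|r| = sigma * sqrt(2/pi)`). The band is the fitted mean line plus/minus
#' `multiplier` fitted SDs. This reduces to the classic construction when the
#' difference is unrelated to the mean and the spread is constant.
#'
#' @inheritParams ba_classic
#' @param min_n minimum pairs per stratum (default 10).
#' @return tibble of class `agreement_curve` (see [ba_classic()]); the fitted
#'   coefficients are kept in attribute `fits` (per stratum: `beta` for the
#'   mean line, `gamma` for the absolute-residual line).
#' @export
ba_regression <- function(pe, multiplier = 2, grid_n = 100, min_n = 10) {
  fits <- list()
  out <- lapply(split(pe, pe$stratum), function(s) {
    st <- s$stratum[1]
    if (nrow(s) < min_n) {
      stop("regression limits of agreement need >= ", min_n,
           " pairs in stratum '", st, "' (got ", nrow(s), ")", call. = FALSE)
    }
    if (var(s$m) == 0) {
      warning("pairwise means are constant in stratum '", st,
              "'; falling back to classic limits of agreement", call. = FALSE)
      cb <- ba_classic(s, multiplier = multiplier, grid_n = grid_n)
      cb$method <- "linear_regression"
      return(cb)
    }
    fit_d <- lm(d ~ m, data = s)
    fit_s <- lm(abs(resid(fit_d)) ~ s$m)
    g <- loa_grid(s$m, grid_n)
    dhat <- coef(fit_d)[1] + coef(fit_d)[2] * g
    sdm <- sqrt(pi / 2) * (coef(fit_s)[1] + coef(fit_s)[2] * g)
    if (any(sdm < 0)) {
      warning("fitted SD negative at the edge of the m range in stratum '",
              st, "'; clamped to 0", call. = FALSE)
      sdm <- pmax(sdm, 0)
    }
    fits[[st]] <<- list(beta = unname(coef(fit_d)),
                        gamma = unname(coef(fit_s)),
                        sd_slope = sqrt(pi / 2) * unname(coef(fit_s)[2]))
    curve_tibble(st, g, dhat, dhat - multiplier * sdm, dhat + multiplier * sdm,
                 "linear_regression", nrow(s))
  })
  res <- as_agreement_curve(dplyr::bind_rows(out), pe)
  attr(res, "fits") <- fits
  res
}

#' Quantile-regression limits of agreement
#'
#' Linear quantile-regression lines of d on m at the requested quantiles;
#' with the default `taus` the band is the fitted 2.5%/97.5% lines and the
#' centre line the conditional median. Preferred when the differences are
#' strongly non-normal or the two methods' distributions differ in shape.
#'
#' @inheritParams ba_classic
#' @param taus quantile levels for (lower, centre, upper); default
#'   `c(0.025, 0.5, 0.975)`.
#' @param min_n minimum pairs per stratum (default 50; the tail quantile fits
#'   are unstable below that).
#' @return tibble of class `agreement_curve` (see [ba_classic()]).
#' @export
ba_quantile <- function(pe, taus = c(0.025, 0.5, 0.975), grid_n = 100,
                        min_n = 50) {
  stopifnot(length(taus) == 3, all(diff(taus) > 0))
  out <- lapply(split(pe, pe$stratum), function(s) {
    st <- s$stratum[1]
    if (nrow(s) < min_n) {
      stop("quantile limits of agreement need >= ", min_n,
           " pairs in stratum '", st, "' (got ", nrow(s), ")", call. = FALSE)
    }
    g <- loa_grid(s$m, grid_n)
    lines <- lapply(taus, function(tau) {
      fit <- tryCatch(
        suppressWarnings(quantreg::rq(d ~ m, tau = tau, data = s)),
        error = function(e) {
          stop("quantile regression failed to converge in stratum '", st,
               "' at tau = ", tau, ": ", conditionMessage(e), call. = FALSE)
        })
      coef(fit)[1] + coef(fit)[2] * g
    })
    curve_tibble(st, g, lines[[2]], lines[[1]], lines[[3]],
                 "quantile_regression", nrow(s))
  })
  as_agreement_curve(dplyr::bind_rows(out), pe)
}

as_agreement_curve <- function(curve, pe) {
  structure(curve,
            eq_a = attr(pe, "eq_a"), eq_b = attr(pe, "eq_b"),
            class = unique(c("agreement_curve", class(curve))))
}

#' Empirical coverage of a limits-of-agreement band
#'
#' Fraction of observed differences lying inside `[lower, upper]` evaluated at
#' each subject's m by linear interpolation of the fitted curves (flat
#' extrapolation at the grid edges). Around 0.95 is expected for
#' approximately normal differences.
#'
#' @param curve an agreement curve from [ba_classic()], [ba_regression()] or
#'   [ba_quantile()].
#' @param pe the paired estimates the curve was fitted to (or held-out pairs).
#' @return tibble: `stratum`, `n`, `coverage` (fraction in \[0, 1\]).
#' @export
loa_coverage <- function(curve, pe) {
  out <- lapply(split(pe, pe$stratum), function(s) {
    cs <- curve[curve$stratum == s$stratum[1], ]
    if (nrow(cs) == 0) return(NULL)
    lo <- approx(cs$m, cs$lower, xout = s$m, rule = 2)$y
    up <- approx(cs$m, cs$upper, xout = s$m, rule = 2)$y
    tibble::tibble(stratum = s$stratum[1], n = nrow(s),
                   coverage = mean(s$d >= lo & s$d <= up))
  })
  dplyr::bind_rows(out)
}
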