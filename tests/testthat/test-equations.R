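# Independent one-line oracles for every equation, kept deliberately separate
# from the package implementation (no shared helpers, no piecewise branching
# tricks: the CKD-EPI oracle picks the exponent with a plain if).
oracle <- list(
  cockcroft_gault = function(age, weight, sex, scr)
    (140 - age) * weight * (if (sex == "female") 0.85 else 1) / (72 * scr),
  mdrd4 = function(scr, age, sex, black)
    175 * scr^-1.154 * age^-0.203 * (if (black) 1.212 else 1) *
      (if (sex == "female") 0.742 else 1),
  ckd_epi_cr = function(scr, age, sex, black) {
    k <- if (sex == "female") 0.7 else 0.9
    a <- if (sex == "female") -0.329 else -0.411
    cf <- if (sex == "female") (if (black) 166 else 144) else
      (if (black) 163 else 141)
    cf * (scr / k)^(if (scr <= k) a else -1.209) * 0.993^age
  },
  van_deventer = function(scysc, age) 10^(2.35 - 0.33 * scysc - 0.003 * age),
  cysc_simple = function(scysc) 76.7 * scysc^-1.19,
  cysc_full = function(scysc, age, sex, black)
    127.7 * scysc^-1.17 * age^-0.13 * (if (sex == "female") 0.91 else 1) *
      (if (black) 1.06 else 1)
)

test_that("worked examples match direct evaluation", {
  expect_equal(egfr_cockcroft_gault(40, 72, "male", 1.0), 100,
               ignore_attr = TRUE)
  expect_equal(egfr_cockcroft_gault(40, 72, "female", 1.0), 85,
               ignore_attr = TRUE)
  expect_equal(as.numeric(egfr_cockcroft_gault(31, 65, "male", 0.73)),
               134.798325722983, tolerance = 1e-12)
  expect_equal(egfr_mdrd4(1.0, 30, "male"), 87.7369300054927,
               tolerance = 1e-12)
  expect_equal(egfr_ckd_epi_cr(0.7, 50, "female"), 101.350271601111,
               tolerance = 1e-12)
  expect_equal(egfr_van_deventer(1.0, 50), 74.1310241300918,
               tolerance = 1e-12)
  expect_equal(egfr_van_deventer(0.78, 31), 99.9079389984462,
               tolerance = 1e-12)
  expect_equal(egfr_ckd_epi_cysc(1.0, variant = "simple"), 76.7)
  expect_equal(egfr_ckd_epi_cysc(0.78, variant = "simple"),
               103.086735483148, tolerance = 1e-12)
  expect_equal(egfr_ckd_epi_cysc(1.0, 40, "male", variant = "full",
                                 black_factor = TRUE),
               83.7970950931503, tolerance = 1e-12)
})

test_that("every variant matches its oracle on 1000 random valid subjects", {
  subj <- random_subjects(1000)
  rel_err <- function(x, y) max(abs(x - y) / abs(y))
  ora_vec <- function(f, ...) mapply(f, ...)
  expect_lt(rel_err(
    as.numeric(egfr_cockcroft_gault(subj$age, subj$weight, subj$sex, subj$scr)),
    ora_vec(oracle$cockcroft_gault, subj$age, subj$weight, subj$sex, subj$scr)),
    1e-9)
  for (black in c(FALSE, TRUE)) {
    expect_lt(rel_err(
      egfr_mdrd4(subj$scr, subj$age, subj$sex, black),
      ora_vec(oracle$mdrd4, subj$scr, subj$age, subj$sex, black)), 1e-9)
    expect_lt(rel_err(
      egfr_ckd_epi_cr(subj$scr, subj$age, subj$sex, black),
      ora_vec(oracle$ckd_epi_cr, subj$scr, subj$age, subj$sex, black)), 1e-9)
    expect_lt(rel_err(
      egfr_ckd_epi_cysc(subj$scysc, subj$age, subj$sex, "full", black),
      ora_vec(oracle$cysc_full, subj$scysc, subj$age, subj$sex, black)), 1e-9)
  }
  expect_lt(rel_err(egfr_van_deventer(subj$scysc, subj$age),
                    ora_vec(oracle$van_deventer, subj$scysc, subj$age)), 1e-9)
  expect_lt(rel_err(egfr_ckd_epi_cysc(subj$scysc, variant = "simple"),
                    ora_vec(oracle$cysc_simple, subj$scysc)), 1e-9)
})

test_that("black-factor on/off ratios are the exact printed constants", {
  subj <- random_subjects(50)
  expect_equal(egfr_mdrd4(subj$scr, subj$age, subj$sex, TRUE) /
                 egfr_mdrd4(subj$scr, subj$age, subj$sex, FALSE),
               rep(1.212, 50))
  ratio <- egfr_ckd_epi_cr(subj$scr, subj$age, subj$sex, TRUE) /
    egfr_ckd_epi_cr(subj$scr, subj$age, subj$sex, FALSE)
  expect_equal(ratio, ifelse(subj$sex == "female", 166 / 144, 163 / 141))
  expect_equal(
    egfr_ckd_epi_cysc(subj$scysc, subj$age, subj$sex, "full", TRUE) /
      egfr_ckd_epi_cysc(subj$scysc, subj$age, subj$sex, "full", FALSE),
    rep(1.06, 50))
})

test_that("sex factors are the exact printed constants", {
  expect_equal(egfr_mdrd4(1.2, 40, "female") / egfr_mdrd4(1.2, 40, "male"),
               0.742)
  expect_equal(as.numeric(egfr_cockcroft_gault(40, 70, "female", 1.2) /
                            egfr_cockcroft_gault(40, 70, "male", 1.2)), 0.85)
  expect_equal(egfr_ckd_epi_cysc(0.9, 40, "female", "full") /
                 egfr_ckd_epi_cysc(0.9, 40, "male", "full"), 0.91)
})

test_that("CKD-EPI creatinine is continuous across the knot", {
  for (sex in c("female", "male")) {
    for (black in c(FALSE, TRUE)) {
      k <- if (sex == "female") 0.7 else 0.9
      left <- egfr_ckd_epi_cr(k - 1e-9, 50, sex, black)
      right <- egfr_ckd_epi_cr(k + 1e-9, 50, sex, black)
      expect_lt(abs(left - right), 1e-4)
    }
  }
})

test_that("all equations are strictly decreasing in their biomarker", {
  scr_grid <- seq(0.3, 6, length.out = 60)
  cys_grid <- seq(0.4, 4, length.out = 60)
  for (sex in c("female", "male")) {
    expect_true(all(diff(as.numeric(
      egfr_cockcroft_gault(rep(50, 60), 70, sex, scr_grid))) < 0))
    expect_true(all(diff(egfr_mdrd4(scr_grid, 50, sex)) < 0))
    expect_true(all(diff(egfr_ckd_epi_cr(scr_grid, 50, sex)) < 0))
    expect_true(all(diff(
      egfr_ckd_epi_cysc(cys_grid, 50, sex, "full")) < 0))
  }
  expect_true(all(diff(egfr_van_deventer(cys_grid, 50)) < 0))
  expect_true(all(diff(egfr_ckd_epi_cysc(cys_grid, variant = "simple")) < 0))
})

test_that("domain errors are raised with the equation named", {
  expect_error(egfr_cockcroft_gault(200, 70, "male", 1.0), "140")
  expect_error(egfr_cockcroft_gault(40, NA, "male", 1.0), "Cockcroft-Gault")
  expect_error(egfr_mdrd4(-1, 40, "male"), "MDRD-4")
  expect_error(egfr_ckd_epi_cr(0, 40, "male"), "CKD-EPI")
  expect_error(egfr_van_deventer(-0.5, 40), "van Deventer")
  expect_error(egfr_ckd_epi_cysc(1.0, variant = "simple", black_factor = TRUE),
               "black")
  expect_error(egfr_ckd_epi_cysc(1.0, variant = "full"), "age and sex")
  expect_error(normalize_sex("banana"), "sex")
})

test_that("panel evaluation is consistent with the individual operations", {
  co <- tiny_cohort()
  p <- egfr_panel(co)
  expect_equal(ncol(p) - 2, 9)  # id + hiv_status + nine variants
  expect_true(all(vapply(p[, egfr_equations()$equation],
                         function(x) all(is.finite(x) & x > 0), logical(1))))
  expect_equal(p$mdrd4, egfr_mdrd4(co$scr, co$age, co$sex))
  expect_equal(p$ckd_epi_cr_black,
               egfr_ckd_epi_cr(co$scr, co$age, co$sex, TRUE))
  p1 <- egfr_panel(co, "van_deventer")
  expect_named(p1, c("id", "hiv_status", "van_deventer"))
  expect_equal(attr(p, "units")[["cockcroft_gault"]], "mL/min")
  expect_error(egfr_panel(co, "not_an_equation"), "unknown")
})
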