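test_that("pairing computes means, differences and strata correctly", {
  panel <- tibble::tibble(id = 1:2, x = c(100, 90), y = c(80, 90),
                          grp = c("p", "n"))
  pe <- pair_estimates(panel, "x", "y")
  expect_equal(pe$m, c(90, 90))
  expect_equal(pe$d, c(20, 0))
  expect_equal(pe$stratum, c("all", "all"))
  pes <- pair_estimates(panel, "x", "y", stratify_by = "grp")
  expect_setequal(pes$stratum, c("p", "n"))
  expect_equal(sum(table(pes$stratum)), nrow(panel))
  # identical methods give all-zero differences
  pe0 <- pair_estimates(panel, "x", "x")
  expect_equal(pe0$d, c(0, 0))
  # missing values are excluded and counted
  panel$y[1] <- NA
  expect_message(pe1 <- pair_estimates(panel, "x", "y"), "1 subject")
  expect_equal(nrow(pe1), 1)
  expect_equal(attr(pe1, "n_excluded"), 1)
})

test_that("classic limits of agreement are mean +/- 2 sample SD", {
  pe <- simulate_pairs(3, seed = 1)
  pe$d <- c(-1, 0, 1)  # sd = 1
  curve <- ba_classic(pe)
  expect_equal(unique(curve$mean_diff), 0)
  expect_equal(unique(curve$lower), -2)
  expect_equal(unique(curve$upper), 2)
  expect_equal(unique(curve$method), "classic")
  # constant differences give a zero-width band
  pe$d <- rep(2.5, 3)
  czw <- ba_classic(pe)
  expect_equal(unique(czw$lower), 2.5)
  expect_equal(unique(czw$upper), 2.5)
  expect_error(ba_classic(simulate_pairs(2, seed = 1)), ">= 3")
})

test_that("classic band holds ~95.4% of normal differences", {
  pe <- simulate_pairs(1e5, seed = 7)
  cov <- loa_coverage(ba_classic(pe), pe)
  expect_equal(cov$coverage, 0.9545, tolerance = 0.005)
})

test_that("regression limits fit the mean-difference line exactly on
           noise-free proportional data", {
  pe <- simulate_pairs(100, seed = 3, sd_fun = function(m) 0)
  pe$d <- 0.1 * pe$m
  pe$a <- pe$m + pe$d / 2
  pe$b <- pe$m - pe$d / 2
  curve <- ba_regression(pe)
  expect_equal(curve$mean_diff, 0.1 * curve$m, tolerance = 1e-10)
  expect_equal(curve$upper, curve$lower, tolerance = 1e-8)
})

test_that("on homoscedastic data the regression band matches the classic
           band and both cover ~95%", {
  pe <- simulate_pairs(1e4, seed = 11, sd_fun = function(m) 8)
  classic <- ba_classic(pe)
  regr <- ba_regression(pe)
  width_c <- mean(classic$upper - classic$lower)
  width_r <- mean(regr$upper - regr$lower)
  expect_equal(width_r, width_c, tolerance = 0.05)
  expect_equal(loa_coverage(classic, pe)$coverage, 0.95, tolerance = 0.021)
  expect_equal(loa_coverage(regr, pe)$coverage, 0.95, tolerance = 0.021)
})

test_that("regression recovers a linearly increasing residual SD", {
  truth_slope <- 0.15
  pe <- simulate_pairs(1e4, seed = 13,
                       sd_fun = function(m) 2 + truth_slope * m)
  fit <- attr(ba_regression(pe), "fits")$all
  expect_equal(fit$sd_slope, truth_slope, tolerance = 0.10)
  # band ordering holds on the whole grid
  curve <- ba_regression(pe)
  expect_true(all(curve$lower <= curve$mean_diff))
  expect_true(all(curve$mean_diff <= curve$upper))
})

test_that("regression falls back to classic when the means are degenerate", {
  pe <- simulate_pairs(20, seed = 5)
  pe$m <- rep(100, 20)
  expect_warning(curve <- ba_regression(pe), "classic")
  expect_equal(unique(curve$mean_diff), mean(pe$d))
  expect_equal(unique(curve$method), "linear_regression")
})

test_that("quantile limits match an independent pinball-loss minimiser", {
  pe <- simulate_pairs(500, seed = 17, sd_fun = function(m) 4)
  curve <- ba_quantile(pe)
  # oracle: direct Nelder-Mead minimisation of the check loss
  pinball_fit <- function(tau) {
    loss <- function(beta) {
      r <- pe$d - beta[1] - beta[2] * pe$m
      sum(r * (tau - (r < 0)))
    }
    optim(c(median(pe$d), 0), loss, method = "Nelder-Mead",
          control = list(maxit = 5000, reltol = 1e-12))$par
  }
  for (spec in list(list(tau = 0.5, col = "mean_diff"),
                    list(tau = 0.025, col = "lower"),
                    list(tau = 0.975, col = "upper"))) {
    beta <- pinball_fit(spec$tau)
    grid_line <- beta[1] + beta[2] * curve$m
    # compare fitted values across the grid, on the scale of the data spread
    expect_lt(max(abs(curve[[spec$col]] - grid_line)) / sd(pe$d), 0.05)
  }
})

test_that("quantile band covers ~95% and the median line tracks skew", {
  pe <- simulate_pairs(1e4, seed = 19, sd_fun = function(m) 6)
  cov <- loa_coverage(ba_quantile(pe), pe)
  expect_equal(cov$coverage, 0.95, tolerance = 0.021)
  # median line of symmetric data ~ mean line of the regression construction
  qmed <- ba_quantile(pe)$mean_diff
  rmean <- ba_regression(pe)$mean_diff
  expect_lt(max(abs(qmed - rmean)) / sd(pe$d), 0.05)
  # lognormal (right-skewed) noise pulls the median below the mean
  skewed <- simulate_pairs(1e4, seed = 23, sd_fun = function(m) 5,
                           rdist = function(n) rlnorm(n) - exp(0.5))
  qskew <- ba_quantile(skewed)$mean_diff
  rskew <- ba_regression(skewed)$mean_diff
  expect_true(mean(qskew) < mean(rskew))
  expect_error(ba_quantile(simulate_pairs(30, seed = 1)), ">= 50")
})

test_that("strata are fitted independently (no cross-stratum leakage)", {
  pe1 <- simulate_pairs(200, seed = 29, beta0 = 10)
  pe2 <- simulate_pairs(200, seed = 31, beta0 = -10)
  pe1$stratum <- "g1"
  pe2$stratum <- "g2"
  pe1$id <- paste0("x", pe1$id)
  pooled <- rbind(pe1, pe2)
  attr(pooled, "eq_a") <- "A"; attr(pooled, "eq_b") <- "B"
  class(pooled) <- class(pe1)
  cp <- ba_regression(pooled)
  c1 <- ba_regression(pe1)
  expect_equal(cp[cp$stratum == "g1", ]$mean_diff, c1$mean_diff)
  expect_equal(cp[cp$stratum == "g1", ]$upper, c1$upper)
})

test_that("agreement curves serialize to the tidy plot-data contract", {
  pe <- simulate_pairs(100, seed = 37)
  curve <- ba_regression(pe)
  expect_named(tibble::as_tibble(curve),
               c("stratum", "m", "mean_diff", "lower", "upper", "method", "n"))
  expect_equal(nrow(curve), 100)  # one stratum x 100 grid points
  tmp <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(curve, tmp)
  back <- readr::read_csv(tmp, show_col_types = FALSE)
  expect_equal(back$upper, curve$upper)
})
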