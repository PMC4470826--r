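# Shared fixtures: tiny hand-written cohorts and random valid subject draws.

tiny_cohort <- function() {
  tibble::tibble(
    id = c("a", "b", "c", "d"),
    age = c(31, 45, 28, 60),
    sex = c("male", "female", "female", "male"),
    weight = c(65, 58, 52, 80),
    height = c(1.68, 1.55, 1.60, 1.72),
    hiv_status = c("positive", "negative", "positive", "negative"),
    scr = c(0.73, 0.90, 0.65, 1.40),
    scysc = c(0.87, 0.75, 0.95, 1.60))
}

# random valid subject records spanning a wide biomarker range
random_subjects <- function(n, seed = 42) {
  withr::with_seed(seed, tibble::tibble(
    id = as.character(seq_len(n)),
    age = runif(n, 18, 95),
    sex = sample(c("female", "male"), n, replace = TRUE),
    weight = runif(n, 35, 120),
    scr = exp(runif(n, log(0.3), log(8))),
    scysc = exp(runif(n, log(0.4), log(5)))))
}

# simulated paired estimates with controllable mean-difference line and
# residual scale; sd_fun maps m to the residual SD
simulate_pairs <- function(n, seed, beta0 = 0, beta1 = 0,
                           sd_fun = function(m) 5,
                           m_range = c(40, 140),
                           rdist = rnorm) {
  withr::with_seed(seed, {
    m <- runif(n, m_range[1], m_range[2])
    d <- beta0 + beta1 * m + sd_fun(m) * rdist(n)
    a <- m + d / 2
    b <- m - d / 2
    structure(tibble::tibble(id = as.character(seq_len(n)),
                             stratum = "all", a = a, b = b, m = m, d = d),
              eq_a = "A", eq_b = "B",
              class = c("paired_estimates", "tbl_df", "tbl", "data.frame"))
  })
}
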