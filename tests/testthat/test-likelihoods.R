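params <- raw_params(0.054, 2.6, 0.006)

test_that("delta-method precision follows the reported standard error", {
  expect_equal(logit_precision_from_se(0.8, 0.05), 10.24)
  expect_equal(logit_precision_from_se(0.5, 0.03), 0.0625 / 0.03^2)
  # vague in the wide-SE limit
  expect_lt(logit_precision_from_se(0.8, 100), 1e-5)
  expect_error(logit_precision_from_se(1, 0.05), "strictly inside")
  expect_error(logit_precision_from_se(0.8, 0), "positive")
})

test_that("delta-method precision agrees with Monte-Carlo logit spread", {
  set.seed(31)
  for (case in list(c(0.8, 0.02), c(0.6, 0.03), c(0.95, 0.005), c(0.7, 0.04))) {
    x <- rnorm(4e5, case[1], case[2])
    x <- x[x > 0 & x < 1]
    tau <- logit_precision_from_se(case[1], case[2])
    expect_equal(sd(qlogis(x)), 1 / sqrt(tau), tolerance = 0.05)
  }
})

test_that("precision fallbacks follow the documented rule order", {
  expect_equal(precision_from_fallbacks(0.8, n = 100), 16)
  expect_equal(precision_from_fallbacks(0.7, ci_lo = 0.6, ci_hi = 0.8),
               16.9408334, tolerance = 1e-7)
  expect_equal(precision_from_fallbacks(0.7), 1)            # default logit SD 1
  expect_equal(precision_from_fallbacks(0.7, default_logit_sd = 0.5), 4)
  # SE wins over CI and n
  expect_equal(precision_from_fallbacks(0.8, se = 0.05, ci_lo = 0.7, ci_hi = 0.9,
                                        n = 10), 10.24)
  expect_error(precision_from_fallbacks(0.7, ci_lo = 0.8, ci_hi = 0.6), "lower bound")
  expect_error(precision_from_fallbacks(0.95, ci_lo = 0.6, ci_hi = 0.8), "outside")
})

test_that("pulse harvest multiplies natural annual survival by 1 - h", {
  phi_nat <- annual_survival(params, 3, mult = 1.2)
  expect_equal(harvest_adjusted_annual_survival(params, 3, h = 0, mult = 1.2), phi_nat)
  expect_equal(harvest_adjusted_annual_survival(params, 3, h = 0.5, mult = 1.2),
               0.5 * phi_nat)
  expect_error(harvest_adjusted_annual_survival(params, 3, h = 1), "\\[0, 1)")
  expect_error(harvest_adjusted_annual_survival(params, 3, h = -0.1), "\\[0, 1)")
})

test_that("range weights are normalised expected abundances", {
  expect_identical(range_weights(params, 4, 4), 1)
  # geometric under constant hazard
  p_const <- raw_params(1e-12, 2, 0.2)
  w <- range_weights(p_const, 1, 6, h = 0.1)
  phi <- (1 - 0.1) * exp(-0.2)
  expect_equal(w / w[1], phi^(0:5), tolerance = 1e-6)
  # brute-force cohort projection oracle, harvested and not
  for (uh in c(TRUE, FALSE)) {
    w <- range_weights(params, 2, 9, h = 0.15, mult = 1.4, use_harvest = uh)
    expect_equal(w, cohort_projection_weights(params, 2, 9, h = 0.15, psi = 1.4,
                                              use_harvest = uh), tolerance = 1e-12)
  }
  expect_error(range_weights(params, 5, 3), "t1")
})

test_that("range weights sum to one over random parameter draws", {
  set.seed(7)
  for (i in 1:25) {
    p <- raw_params(runif(1, 0.01, 0.3), 1 + runif(1, 0.2, 4), runif(1, 0, 0.1))
    t1 <- sample(0:10, 1); t2 <- t1 + sample(0:15, 1)
    w <- range_weights(p, t1, t2, h = runif(1, 0, 0.4), mult = exp(rnorm(1, 0, 0.5)))
    expect_equal(sum(w), 1, tolerance = 1e-12)
    expect_true(all(w > 0))
  }
})

test_that("range survival is the abundance-weighted mean annual survival", {
  p_const <- raw_params(1e-12, 2, 0.2)
  phi <- (1 - 0.05) * exp(-0.2)
  expect_equal(range_survival(p_const, 1, 8, h = 0.05), phi, tolerance = 1e-6)
  expect_equal(range_survival(params, 4, 4, h = 0.1),
               harvest_adjusted_annual_survival(params, 4, h = 0.1))
  w <- cohort_projection_weights(params, 1, 5, h = 0.1, psi = 0.8)
  phis <- harvest_adjusted_annual_survival(params, 1:5, h = 0.1, mult = 0.8)
  expect_equal(range_survival(params, 1, 5, h = 0.1, mult = 0.8),
               sum(w * phis), tolerance = 1e-12)
  expect_gte(range_survival(params, 1, 5, h = 0.1, mult = 0.8), min(phis))
  expect_lte(range_survival(params, 1, 5, h = 0.1, mult = 0.8), max(phis))
})

test_that("logit-normal log densities behave like normal densities", {
  phi <- harvest_adjusted_annual_survival(params, 2, h = 0.1, mult = 1.1)
  # at the mode the density is the normalising constant
  expect_equal(age_specific_loglik(phi, 2, tau = 9, params, h = 0.1, mult = 1.1),
               0.5 * log(9 / (2 * pi)))
  # doubling the precision at fixed residual
  est <- plogis(qlogis(phi) + 0.3)
  l1 <- age_specific_loglik(est, 2, tau = 5, params, h = 0.1, mult = 1.1)
  l2 <- age_specific_loglik(est, 2, tau = 10, params, h = 0.1, mult = 1.1)
  expect_equal(l2 - l1, 0.5 * log(2) - 0.3^2 * 5 / 2, tolerance = 1e-10)
  # reference-density summation over a simulated dataset
  set.seed(5)
  ages <- sample(0:8, 12, replace = TRUE)
  taus <- runif(12, 2, 30)
  ests <- plogis(rnorm(12, qlogis(harvest_adjusted_annual_survival(params, ages, h = 0.1)), 0.4))
  total <- sum(mapply(function(e, a, tau)
    age_specific_loglik(e, a, tau, params, h = 0.1), ests, ages, taus))
  ref <- sum(dnorm(qlogis(ests),
                   qlogis(harvest_adjusted_annual_survival(params, ages, h = 0.1)),
                   1 / sqrt(taus), log = TRUE))
  expect_equal(total, ref, tolerance = 1e-10)
})

test_that("age-range log density mirrors the age-specific one", {
  phi_r <- range_survival(params, 1, 4, h = 0.05)
  expect_equal(age_range_loglik(phi_r, 1, 4, tau = 16, params, h = 0.05),
               0.5 * log(16 / (2 * pi)))
  est <- plogis(qlogis(phi_r) - 0.25)
  l1 <- age_range_loglik(est, 1, 4, tau = 4, params, h = 0.05)
  l2 <- age_range_loglik(est, 1, 4, tau = 8, params, h = 0.05)
  expect_equal(l2 - l1, 0.5 * log(2) - 0.25^2 * 4 / 2, tolerance = 1e-10)
  expect_equal(age_range_loglik(est, 1, 4, tau = 4, params, h = 0.05),
               dnorm(qlogis(est), qlogis(phi_r), 1 / sqrt(4), log = TRUE),
               tolerance = 1e-10)
})

test_that("catch cell probabilities are the cohort-projection age structure", {
  expect_identical(catch_cell_probs(params, 1), 1)
  p_const <- raw_params(1e-12, 2, 0.2)
  pr <- catch_cell_probs(p_const, 8, h = 0.1)
  phi <- (1 - 0.1) * exp(-0.2)
  expect_equal(pr / pr[1], phi^(0:7), tolerance = 1e-6)
  expect_equal(catch_cell_probs(params, 10, h = 0.12, mult = 1.3),
               cohort_projection_weights(params, 1, 10, h = 0.12, psi = 1.3),
               tolerance = 1e-12)
  expect_equal(sum(catch_cell_probs(params, 25, h = 0.3)), 1, tolerance = 1e-12)
})

test_that("catch-at-age likelihood is the multinomial log-pmf", {
  # all mass in one cell
  counts <- c(0, 0, 40, 0)
  pr <- catch_cell_probs(params, 4, h = 0.1)
  expect_equal(catch_at_age_loglik(counts, params, h = 0.1),
               40 * log(pr[3]), tolerance = 1e-12)
  # reference pmf on random fixtures
  set.seed(17)
  for (i in 1:10) {
    n_ages <- sample(3:12, 1)
    counts <- as.integer(rmultinom(1, 150, rep(1 / n_ages, n_ages)))
    h <- runif(1, 0, 0.3); psi <- exp(rnorm(1, 0, 0.4))
    pr <- catch_cell_probs(params, n_ages, h = h, mult = psi)
    expect_equal(catch_at_age_loglik(counts, params, h = h, mult = psi),
                 ref_multinom_logpmf(counts, pr), tolerance = 1e-10)
  }
  expect_error(catch_at_age_loglik(c(0, 0), params), "positive total")
  expect_error(catch_at_age_loglik(c(-1, 5), params), "non-negative")
})

test_that("with no harvest and unit multiplier the means are pure baseline quantities", {
  expect_equal(harvest_adjusted_annual_survival(params, 0:5),
               annual_survival(params, 0:5))
  expect_equal(range_survival(params, 1, 4),
               sum(range_weights(params, 1, 4) *
                     annual_survival(params, 1:4)))
})
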