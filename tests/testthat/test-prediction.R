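# one moderately sized fit shared by the prediction tests
fit_env <- new.env()
get_fixture_fit <- function() {
  if (is.null(fit_env$fit)) {
    fx <- phocid_fixture()
    m <- build_model(fx$data, model_spec(c("subfamily", "species", "dataset")))
    fit_env$model <- m
    fit_env$fit <- run_mcmc(m, n_chains = 2, n_iter = 3000, burn_in = 1000,
                            thin = 2, seed = 77)
  }
  list(fit = fit_env$fit, model = fit_env$model)
}

test_that("dataset-level curves are plain per-draw multiplier curves", {
  fm <- get_fixture_fit()
  cv <- curve_at_level(fm$fit, fm$model, "dataset", "d01", ages = c(0, 1, 5, 10))
  # manual recomputation from the pooled draws (no bias correction applies)
  u <- natmort:::pooled_draws(fm$fit)
  a <- exp(u[, "log_a"]); b <- 1 + exp(u[, "log_bm1"]); cc <- exp(u[, "log_c"])
  ds <- fm$model$data$datasets[fm$model$data$datasets$dataset_id == "d01", ]
  psi <- exp(u[, "eps[subfamily:sf01]"] +
               u[, paste0("eps[species:", ds$species, "]")] +
               u[, "eps[dataset:d01]"])
  S10 <- exp(-psi * ((a * 10)^b + (a * 10)^(1 / b) + cc * 10))
  expect_equal(cv$S_mean[cv$age == 10], mean(S10), tolerance = 1e-10)
  expect_equal(cv$S_lo[cv$age == 10], unname(quantile(S10, 0.025)), tolerance = 1e-10)
  expect_equal(cv$S_mean[cv$age == 0], 1)
  expect_true(is.na(cv$hazard_mean[cv$age == 0]))
})

test_that("higher-level curves apply the lognormal bias correction per draw", {
  fm <- get_fixture_fit()
  cv <- curve_at_level(fm$fit, fm$model, "species", "sp01", ages = c(5, 10))
  u <- natmort:::pooled_draws(fm$fit)
  a <- exp(u[, "log_a"]); b <- 1 + exp(u[, "log_bm1"]); cc <- exp(u[, "log_c"])
  tau_d <- exp(u[, "log_tau[dataset]"])
  psi <- exp(u[, "eps[subfamily:sf01]"] + u[, "eps[species:sp01]"] + 0.5 / tau_d)
  S5 <- exp(-psi * ((a * 5)^b + (a * 5)^(1 / b) + cc * 5))
  expect_equal(cv$S_mean[cv$age == 5], mean(S5), tolerance = 1e-10)
})

test_that("master-level multipliers match Monte-Carlo marginalisation of the effects", {
  # the bias correction reports the real-scale mean multiplier
  # E[exp(sum eps)] = exp(0.5 sum 1/tau); check it against simulation of the
  # integrated-out effects, draw by draw
  fm <- get_fixture_fit()
  u <- natmort:::pooled_draws(fm$fit)
  tau_sum <- 1 / exp(u[, "log_tau[subfamily]"]) + 1 / exp(u[, "log_tau[species]"]) +
    1 / exp(u[, "log_tau[dataset]"])
  psi_analytic <- mean(exp(0.5 * tau_sum))
  set.seed(501)
  nmc <- 60
  psi_mc <- sapply(seq_len(nmc), function(i)
    mean(exp(rnorm(nrow(u), 0, sqrt(1 / exp(u[, "log_tau[subfamily]"]))) +
               rnorm(nrow(u), 0, sqrt(1 / exp(u[, "log_tau[species]"]))) +
               rnorm(nrow(u), 0, sqrt(1 / exp(u[, "log_tau[dataset]"]))))))
  expect_equal(psi_analytic, mean(psi_mc),
               tolerance = (3 * sd(psi_mc) / sqrt(nmc) + 0.005) / psi_analytic)
  # and the master curve is the baseline raised to that corrected multiplier,
  # averaged over draws
  cv <- curve_at_level(fm$fit, fm$model, "master", ages = 10)
  a <- exp(u[, "log_a"]); b <- 1 + exp(u[, "log_bm1"]); cc <- exp(u[, "log_c"])
  H10 <- (a * 10)^b + (a * 10)^(1 / b) + cc * 10
  expect_equal(unname(cv$S_mean), mean(exp(-exp(0.5 * tau_sum) * H10)),
               tolerance = 1e-10)
})

test_that("prediction collapses to the species curve when no deeper level exists", {
  fx <- phocid_fixture()
  m <- build_model(fx$data, model_spec("species"))
  f <- run_mcmc(m, n_chains = 2, n_iter = 1200, burn_in = 500, thin = 2, seed = 13)
  sp_curve <- curve_at_level(f, m, "species", "sp02", ages = c(1, 10))
  pred <- predict_prior_population(f, m, "sp02", ages = c(1, 10), seed = 4)
  expect_equal(pred$S_mean, sp_curve$S_mean, tolerance = 1e-12)
  expect_equal(pred$S_lo, sp_curve$S_lo, tolerance = 1e-12)
})

test_that("predictive intervals widen monotonically over the species intervals", {
  fm <- get_fixture_fit()
  ages <- c(1, 5, 10, 20)
  sp_curve <- curve_at_level(fm$fit, fm$model, "species", "sp01", ages = ages)
  pred <- predict_prior_population(fm$fit, fm$model, "sp01", ages = ages, seed = 8)
  expect_true(all(pred$S_hi - pred$S_lo >= sp_curve$S_hi - sp_curve$S_lo))
  # strict containment away from the S(0) = 1 anchor
  expect_true(all(pred$S_lo < sp_curve$S_lo))
  expect_true(all(pred$S_hi > sp_curve$S_hi))
})

test_that("post-hoc simulation and refitting with a missing dataset agree", {
  fx <- phocid_fixture()
  m <- build_model(fx$data, model_spec(c("species", "dataset")))
  f <- run_mcmc(m, n_chains = 2, n_iter = 2500, burn_in = 1000, thin = 2, seed = 19)
  ages <- c(1, 5, 10)
  p_sim <- predict_prior_population(f, m, "sp01", ages = ages, seed = 3)
  p_ref <- predict_prior_population(f, m, "sp01", ages = ages, method = "refit",
                                    seed = 3, n_chains = 2, n_iter = 2500,
                                    burn_in = 1000, thin = 2)
  expect_equal(p_sim$S_mean, p_ref$S_mean, tolerance = 0.04)
  # widths agree to first order only: in the refit the appended effect also
  # feeds back into the dataset-level precision posterior
  expect_equal(p_sim$S_hi - p_sim$S_lo, p_ref$S_hi - p_ref$S_lo, tolerance = 0.2)
})

test_that("unknown keys and inactive levels are rejected", {
  fm <- get_fixture_fit()
  expect_error(curve_at_level(fm$fit, fm$model, "species", "walrus"), "walrus")
  expect_error(curve_at_level(fm$fit, fm$model, "study", "st01"), "not active")
  expect_error(predict_prior_population(fm$fit, fm$model, "walrus"), "walrus")
})
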