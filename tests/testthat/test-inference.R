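test_that("retained draw counts follow the settings arithmetic", {
  target <- list(n_par = 1, log_post = function(th) dnorm(th, log = TRUE),
                 init_fn = function(...) rnorm(1))
  f <- run_mcmc(target, n_chains = 3, n_iter = 300, burn_in = 100, thin = 10, seed = 2)
  expect_equal(dim(f$draws), c(20, 3, 1))
  expect_equal(f$n_retained, 60)
})

test_that("identical seed and settings give identical draws", {
  sim <- tiny_collection()
  m <- build_model(sim$data, model_spec("dataset"))
  f1 <- run_mcmc(m, n_chains = 2, n_iter = 400, burn_in = 200, thin = 2, seed = 9)
  f2 <- run_mcmc(m, n_chains = 2, n_iter = 400, burn_in = 200, thin = 2, seed = 9)
  expect_identical(f1$draws, f2$draws)
  f3 <- run_mcmc(m, n_chains = 2, n_iter = 400, burn_in = 200, thin = 2, seed = 10)
  expect_false(identical(f3$draws, f1$draws))
})

test_that("Gelman-Rubin statistic flags separated chains and passes mixed ones", {
  set.seed(21)
  x <- matrix(rnorm(4000), 1000, 4)
  expect_lt(abs(gelman_rubin(x) - 1), 0.01)
  shifted <- x + matrix(rep(c(0, 0, 5, 5), each = 1000), 1000, 4)
  expect_gt(gelman_rubin(shifted), 1.1)
  expect_error(gelman_rubin(matrix(rnorm(10), 10, 1)), "2 chains")
})

test_that("Gelman-Rubin agrees with the coda reference implementation", {
  skip_if_not_installed("coda")
  set.seed(22)
  for (i in 1:5) {
    x <- matrix(rnorm(3000, sd = runif(1, 0.5, 2)), 500, 6) +
      matrix(rep(rnorm(6, 0, 0.2), each = 500), 500, 6)
    ml <- coda::mcmc.list(lapply(seq_len(ncol(x)), function(j) coda::mcmc(x[, j])))
    ref <- unname(coda::gelman.diag(ml, autoburnin = FALSE, transform = FALSE)$psrf[1, 1])
    # coda applies a small degrees-of-freedom correction on top of the PSRF
    expect_equal(unname(gelman_rubin(x)), ref, tolerance = 0.02)
  }
})

test_that("sampler recovers a conjugate Normal-Normal posterior", {
  # y_i ~ N(mu, s^2), mu ~ N(m0, t0^2): closed-form posterior
  set.seed(33)
  s <- 1.5; m0 <- -1; t0 <- 2
  y <- rnorm(25, 2, s)
  prec_post <- length(y) / s^2 + 1 / t0^2
  mean_post <- (sum(y) / s^2 + m0 / t0^2) / prec_post
  target <- list(
    n_par = 1, par_names = "mu",
    log_post = function(th) sum(dnorm(y, th, s, log = TRUE)) +
      dnorm(th, m0, t0, log = TRUE),
    init_fn = function(...) rnorm(1))
  f <- run_mcmc(target, n_chains = 3, n_iter = 4000, burn_in = 1000, thin = 2, seed = 5)
  draws <- as.numeric(f$draws)
  ess <- min(length(draws) / 10, 1000)     # conservative effective size
  mcse_mean <- sd(draws) / sqrt(ess)
  expect_lt(abs(mean(draws) - mean_post), 3 * mcse_mean)
  expect_equal(var(draws), 1 / prec_post, tolerance = 0.15)
  expect_lt(max(f$rhat), 1.05)
})

test_that("DIC collapses to the deviance for a degenerate posterior", {
  sim <- tiny_collection()
  m <- build_model(sim$data, model_spec("dataset"))
  set.seed(14)
  theta0 <- m$init_fn()
  ll0 <- joint_log_lik(m, theta0)
  fake <- structure(list(
    draws = array(rep(theta0, each = 20 * 2), c(20, 2, m$n_par),
                  dimnames = list(NULL, NULL, m$par_names)),
    logliks = matrix(ll0, 20, 2)), class = "mort_fit")
  d <- dic(fake, m)
  expect_equal(d$pd, 0, tolerance = 1e-8)
  expect_equal(d$dic, -2 * ll0, tolerance = 1e-8)
  expect_equal(d$pd_variance, 0, tolerance = 1e-12)
})

test_that("Spiegelhalter pD matches the conjugate shrinkage weight", {
  # normal mean with known variance: pD = (n/s^2) / (n/s^2 + 1/t0^2)
  set.seed(44)
  s <- 1; t0 <- 1.2; n <- 12
  y <- rnorm(n, 0.5, s)
  target <- list(
    n_par = 1,
    log_post = function(th) sum(dnorm(y, th, s, log = TRUE)) + dnorm(th, 0, t0, log = TRUE),
    log_lik = function(th) sum(dnorm(y, th, s, log = TRUE)),
    init_fn = function(...) rnorm(1))
  f <- run_mcmc(target, n_chains = 3, n_iter = 6000, burn_in = 1000, thin = 2, seed = 6)
  dev <- -2 * as.numeric(f$logliks)
  mu_bar <- mean(f$draws)
  pd <- mean(dev) - (-2 * target$log_lik(mu_bar))
  w <- (n / s^2) / (n / s^2 + 1 / t0^2)
  expect_equal(pd, w, tolerance = 0.1)
})

test_that("posterior for the master hazard contracts as datasets accumulate", {
  width_for <- function(n_datasets, seed) {
    sim <- generate_collection(raw_params(0.054, 2.6, 0.006),
                               taxonomy = simulate_taxonomy(2, 4, 6, n_datasets),
                               level_sd = c(species = 0.2, dataset = 0.2),
                               seed = seed)
    m <- build_model(sim$data, model_spec(c("species", "dataset")))
    f <- run_mcmc(m, n_chains = 2, n_iter = 2500, burn_in = 1000, thin = 3, seed = 100 + seed)
    s <- f$summaries[f$summaries$parameter == "a", ]
    s$q97.5 - s$q2.5
  }
  w10 <- width_for(10, 1)
  w40 <- width_for(40, 1)
  expect_lt(w40, w10)
})

test_that("model selection returns a ranked table and records failures", {
  sim <- tiny_collection()
  specs <- list(model_spec(), model_spec("dataset"))
  tab <- model_select(sim$data, specs, n_chains = 2, n_iter = 800, burn_in = 300,
                      thin = 2, seed = 3)
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$status == "ok"))
  expect_true(!is.unsorted(tab$DIC))
  expect_setequal(tab$model, c("~master", "~master + dataset"))
})

test_that("draw export carries chain and iteration indices", {
  sim <- tiny_collection()
  m <- build_model(sim$data, model_spec("dataset"))
  f <- run_mcmc(m, n_chains = 2, n_iter = 300, burn_in = 100, thin = 4, seed = 1)
  df <- as_draws_df(f, m)
  expect_equal(nrow(df), 100)
  expect_setequal(unique(df$chain), 1:2)
  expect_true(all(c("a", "b", "c", "tau[dataset]") %in% names(df)))
  expect_true(all(df$a > 0) && all(df$b > 1))
})
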