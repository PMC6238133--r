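# Independent oracles used across the suite. These deliberately take the
# "dumb" route (quadrature, brute-force cohort projection, direct density
# summation) so they share no code path with the implementation they check.

# survival via adaptive quadrature of the hazard: S(t) = exp(-psi * int_0^t lambda)
quad_survival <- function(params, t, psi = 1) {
  integrand <- function(x) raw_hazard(params, x)
  v <- stats::integrate(integrand, 0, t, rel.tol = 1e-12, subdivisions = 500L)$value
  exp(-psi * v)
}

# brute-force cohort projection: start 1 individual at t1, multiply forward
# by annual survival, normalise to get expected-abundance weights
cohort_projection_weights <- function(params, t1, t2, h = 0, psi = 1,
                                      use_harvest = TRUE) {
  ages <- t1:t2
  alive <- numeric(length(ages))
  alive[1] <- 1
  for (i in seq_along(ages)[-1]) {
    phi_nat <- annual_survival(params, ages[i - 1], mult = psi)
    step <- if (use_harvest) (1 - h) * phi_nat else phi_nat
    alive[i] <- alive[i - 1] * step
  }
  alive / sum(alive)
}

# reference multinomial log-pmf written out from the lgamma formula
ref_multinom_logpmf <- function(counts, probs) {
  lgamma(sum(counts) + 1) - sum(lgamma(counts + 1)) + sum(counts * log(probs))
}

# reference joint log posterior: sums the package's per-module density
# functions in R, independently of the compiled evaluator used by the
# sampler
ref_joint_log_posterior <- function(model, theta) {
  spec <- model$spec
  cfg <- model$config
  data <- model$data
  ds <- data$datasets
  params <- raw_params(exp(theta[1]), 1 + exp(theta[2]), exp(theta[3]))

  effects <- list()
  for (lev in spec$active_levels)
    effects[[lev]] <- stats::setNames(theta[model$lvl_eff_idx[[lev]]],
                                      model$lvl_groups[[lev]])
  precisions <- sapply(spec$active_levels, function(lev) exp(theta[model$tau_idx[[lev]]]))
  h <- 2 * ds$h_rough * stats::plogis(theta[model$h_idx])

  mult_of <- function(id) {
    i <- match(id, ds$dataset_id)
    assemble_multiplier(list(subfamily = ds$subfamily[i], species = ds$species[i],
                             study = ds$study_id[i], dataset = ds$dataset_id[i]),
                        spec, effects)
  }
  loglik <- 0
  sv <- data$survival
  for (i in seq_len(nrow(sv))) {
    d <- match(sv$dataset_id[i], ds$dataset_id)
    m <- mult_of(sv$dataset_id[i])
    loglik <- loglik + if (sv$type[i] == "age")
      age_specific_loglik(sv$estimate[i], sv$age[i], sv$tau[i], params,
                          h = h[d], mult = m)
    else
      age_range_loglik(sv$estimate[i], sv$t1[i], sv$t2[i], sv$tau[i], params,
                       h = h[d], mult = m,
                       use_harvest = cfg$range_weights_use_harvest)
  }
  ct <- data$catch
  for (i in seq_len(nrow(ct))) {
    d <- match(ct$dataset_id[i], ds$dataset_id)
    loglik <- loglik + catch_at_age_loglik(ct$counts[[i]], params, h = h[d],
                                           mult = mult_of(ct$dataset_id[i]),
                                           first_age = ct$first_age[i],
                                           use_harvest = cfg$range_weights_use_harvest)
  }

  logprior <- sum(stats::dnorm(theta[1:3], cfg$master_prior_mean,
                               cfg$master_prior_sd, log = TRUE))
  if (length(spec$active_levels)) {
    logprior <- logprior +
      log_multiplier_prior(effects, precisions, spec) +
      precision_hyperprior(precisions, spec, cfg) +
      sum(log(precisions))                       # Jacobian of tau = exp(log_tau)
  }
  for (d in seq_len(nrow(ds))) {
    u <- theta[model$h_idx[d]]
    p <- stats::plogis(u)
    logprior <- logprior + harvest_prior(h[d], ds$h_rough[d]) +
      log(2 * ds$h_rough[d]) + log(p) + log(1 - p)   # Jacobian of the logit scaling
  }
  loglik + logprior
}

# map a simulation's ground truth onto a model's unconstrained theta vector
truth_to_theta <- function(model, truth) {
  theta <- numeric(model$n_par)
  p <- truth$params
  theta[1:3] <- c(log(p$a), log(p$b - 1), log(p$c))
  for (lev in model$spec$active_levels) {
    e <- truth$effects[[lev]][model$lvl_groups[[lev]]]
    if (any(is.na(e))) e[is.na(e)] <- 0
    theta[model$lvl_eff_idx[[lev]]] <- e
    sd_k <- truth$level_sd[[lev]]
    theta[model$tau_idx[[lev]]] <- log(1 / max(sd_k, 0.05)^2)
  }
  ds <- model$data$datasets
  h <- truth$h[ds$dataset_id]
  frac <- pmin(pmax(h / (2 * ds$h_rough), 1e-6), 1 - 1e-6)
  theta[model$h_idx] <- stats::qlogis(frac)
  theta
}

# small deterministic collection shared by several fast tests
tiny_collection <- function(seed = 11) {
  generate_collection(raw_params(0.054, 2.6, 0.006),
                      taxonomy = simulate_taxonomy(2, 2, 3, 4),
                      level_sd = c(species = 0.2, dataset = 0.2),
                      age_set = 0:6, seed = seed)
}
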