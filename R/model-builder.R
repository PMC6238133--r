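#' Build the joint posterior for a variance-component model
#'
#' Assembles data, model specification and configuration into a sampler-ready
#' model object: a flat unconstrained parameter vector layout (log a,
#' log(b - 1), log c; taxonomic effects per active level; log precisions;
#' logit-scaled harvest rates per dataset) together with a fast evaluator of
#' the joint log posterior and the data log likelihood.
#'
#' The unconstrained parameterisation keeps the sampler inside the RAW
#' parameter domain (a > 0, b > 1, c > 0) and the precision/harvest supports;
#' Jacobian terms for the precision and harvest transforms are included in
#' the posterior density.
#'
#' @param data A \code{\link{as_mort_data}} collection.
#' @param spec A \code{\link{model_spec}}.
#' @param config A \code{\link{natmort_config}}.
#' @return An object of class \code{mort_model} with elements
#'   \code{par_names}, \code{n_par}, \code{eval} (function returning
#'   \code{c(log_posterior, log_lik)}), \code{init_fn}, and bookkeeping used
#'   by downstream summaries.
#' @export
build_model <- function(data, spec = model_spec(), config = NULL) {
  stopifnot(inherits(data, "mort_data"), inherits(spec, "model_spec"))
  if (is.null(config)) config <- data$config
  ds <- data$datasets
  n_ds <- nrow(ds)

  par_names <- c("log_a", "log_bm1", "log_c")
  # effects, grouped by active level (shallow -> deep), groups sorted
  lvl_groups <- list()
  lvl_eff_idx <- list()
  level_col <- c(subfamily = "subfamily", species = "species",
                 study = "study_id", dataset = "dataset_id")
  for (lev in spec$active_levels) {
    groups <- sort(unique(ds[[level_col[[lev]]]]))
    lvl_groups[[lev]] <- groups
    idx <- length(par_names) + seq_along(groups)
    lvl_eff_idx[[lev]] <- idx
    par_names <- c(par_names, sprintf("eps[%s:%s]", lev, groups))
  }
  tau_idx <- integer(0)
  for (lev in spec$active_levels) {
    tau_idx[lev] <- length(par_names) + 1L
    par_names <- c(par_names, sprintf("log_tau[%s]", lev))
  }
  h_idx <- length(par_names) + seq_len(n_ds)
  par_names <- c(par_names, sprintf("logit_h[%s]", ds$dataset_id))
  n_par <- length(par_names)

  # per-dataset effect index sets K_d
  ds_eff_idx <- lapply(seq_len(n_ds), function(d) {
    idx <- integer(0)
    for (lev in spec$active_levels) {
      g <- ds[[level_col[[lev]]]][d]
      idx <- c(idx, lvl_eff_idx[[lev]][match(g, lvl_groups[[lev]])])
    }
    as.integer(idx - 1L)
  })

  sv <- data$survival
  agev <- sv[sv$type == "age", ]
  rngv <- sv[sv$type == "range", ]
  ct <- data$catch
  ds_index <- function(id) match(id, ds$dataset_id) - 1L
  if (nrow(ct)) {
    too_long <- ct$first_age + lengths(ct$counts) - 1 > config$max_age
    if (any(too_long))
      stop("catch count vector(s) extend beyond max_age (", config$max_age,
           "): cohort ", paste(ct$cohort[too_long], collapse = ", "), call. = FALSE)
  }
  cat_counts <- unlist(ct$counts, use.names = FALSE)
  if (is.null(cat_counts)) cat_counts <- numeric(0)
  cat_len <- as.integer(lengths(ct$counts))
  max_age_needed <- max(0, agev$age, rngv$t2,
                        if (nrow(ct)) ct$first_age + lengths(ct$counts) - 1)
  pack <- list(
    n_datasets = as.integer(n_ds),
    max_age_needed = as.integer(max_age_needed),
    ds_eff_idx = ds_eff_idx,
    h_idx = as.integer(h_idx - 1L),
    h_tilde = as.numeric(ds$h_rough),
    use_harvest = isTRUE(config$range_weights_use_harvest),
    age_ds = as.integer(ds_index(agev$dataset_id)),
    age_t = as.numeric(agev$age),
    age_y = stats::qlogis(agev$estimate),
    age_tau = as.numeric(agev$tau),
    rng_ds = as.integer(ds_index(rngv$dataset_id)),
    rng_t1 = as.integer(rngv$t1), rng_t2 = as.integer(rngv$t2),
    rng_y = stats::qlogis(rngv$estimate), rng_tau = as.numeric(rngv$tau),
    cat_ds = as.integer(ds_index(ct$dataset_id)),
    cat_first = as.integer(ct$first_age),
    cat_off = as.integer(c(0, cumsum(cat_len))[seq_len(nrow(ct))]),
    cat_len = cat_len,
    cat_counts = as.numeric(cat_counts),
    cat_lgamma = vapply(ct$counts, function(cc)
      lgamma(sum(cc) + 1) - sum(lgamma(cc + 1)), numeric(1)),
    master_prior_mean = as.numeric(config$master_prior_mean),
    master_prior_sd = as.numeric(config$master_prior_sd),
    lvl_eff_idx = lapply(unname(lvl_eff_idx), function(i) as.integer(i - 1L)),
    tau_idx = as.integer(tau_idx - 1L),
    tau_alpha = as.numeric(config$tau_alpha[spec$active_levels]),
    tau_beta = as.numeric(config$tau_beta[spec$active_levels])
  )

  init_tau <- config$init_tau
  init_fn <- function(jitter = 0.1) {
    theta <- numeric(n_par)
    theta[1:3] <- config$master_prior_mean + stats::rnorm(3, 0, jitter)
    for (lev in spec$active_levels) {
      theta[lvl_eff_idx[[lev]]] <- stats::rnorm(length(lvl_eff_idx[[lev]]), 0, jitter / 2)
      theta[tau_idx[[lev]]] <- log(init_tau[[lev]]) + stats::rnorm(1, 0, jitter)
    }
    theta[h_idx] <- stats::rnorm(n_ds, 0, jitter)
    theta
  }

  model <- structure(list(
    data = data, spec = spec, config = config,
    par_names = par_names, n_par = n_par,
    lvl_groups = lvl_groups, lvl_eff_idx = lvl_eff_idx,
    tau_idx = tau_idx, h_idx = h_idx,
    master_idx = 1:3,
    pack = pack,
    eval = function(theta) cpp_joint_eval(theta, pack),
    init_fn = init_fn
  ), class = "mort_model")
  model
}

#' @export
print.mort_model <- function(x, ...) {
  cat("Hierarchical mortality model:", format(x$spec), "\n")
  cat(sprintf("  %d parameters; %d datasets; %d survival estimates; %d catch cohorts\n",
              x$n_par, nrow(x$data$datasets), nrow(x$data$survival), nrow(x$data$catch)))
  invisible(x)
}

#' Joint log posterior density
#'
#' Evaluates the unnormalised joint log posterior (sum of all datum log
#' likelihoods, taxonomic-effect priors, precision hyperpriors, harvest
#' priors and master-parameter priors, with transform Jacobians) at an
#' unconstrained parameter vector. Out-of-support or non-finite parameter
#' values return \code{-Inf} rather than raising, so samplers can reject.
#'
#' @param model A \code{\link{build_model}} object.
#' @param theta Numeric parameter vector of length \code{model$n_par}.
#' @return Scalar log density.
#' @export
joint_log_posterior <- function(model, theta) {
  stopifnot(inherits(model, "mort_model"))
  if (length(theta) != model$n_par)
    stop("theta must have length ", model$n_par, call. = FALSE)
  if (anyNA(theta) || any(!is.finite(theta))) return(-Inf)
  model$eval(theta)[1]
}

#' Data log likelihood
#'
#' The data portion of \code{\link{joint_log_posterior}} (the deviance is
#' -2 times this), used for DIC computation.
#'
#' @inheritParams joint_log_posterior
#' @export
joint_log_lik <- function(model, theta) {
  stopifnot(inherits(model, "mort_model"))
  if (anyNA(theta) || any(!is.finite(theta))) return(-Inf)
  model$eval(theta)[2]
}

# map an unconstrained vector to the natural-scale named parameters
theta_to_natural <- function(model, theta) {
  out <- c(a = exp(theta[1]), b = 1 + exp(theta[2]), c = exp(theta[3]))
  for (lev in model$spec$active_levels) {
    e <- theta[model$lvl_eff_idx[[lev]]]
    names(e) <- sprintf("eps[%s:%s]", lev, model$lvl_groups[[lev]])
    out <- c(out, e)
    tau <- exp(theta[model$tau_idx[[lev]]])
    names(tau) <- sprintf("tau[%s]", lev)
    out <- c(out, tau)
  }
  h <- 2 * model$data$datasets$h_rough * stats::plogis(theta[model$h_idx])
  names(h) <- sprintf("h[%s]", model$data$datasets$dataset_id)
  c(out, h)
}
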