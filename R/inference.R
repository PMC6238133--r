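# adapter so the sampler can run on any log-density target, not just
# mort_model objects (used e.g. for conjugate-oracle tests); a generic
# target is a list with n_par, log_post and optionally log_lik, init_fn,
# par_names
as_mcmc_target <- function(model) {
  if (inherits(model, "mort_model")) {
    return(list(n_par = model$n_par, par_names = model$par_names,
                eval = model$eval, init_fn = model$init_fn))
  }
  stopifnot(is.list(model), is.function(model$log_post), is.numeric(model$n_par))
  list(n_par = model$n_par,
       par_names = if (is.null(model$par_names)) paste0("par", seq_len(model$n_par)) else model$par_names,
       eval = if (is.function(model$log_lik))
         function(theta) c(model$log_post(theta), model$log_lik(theta))
       else function(theta) c(model$log_post(theta), NA_real_),
       init_fn = if (is.null(model$init_fn)) function(...) stats::rnorm(model$n_par, 0, 1) else model$init_fn)
}

run_one_chain <- function(target, n_iter, burn_in, thin, adapt_batch = 50,
                          max_init_tries = 25) {
  n_par <- target$n_par
  theta <- NULL
  for (try in seq_len(max_init_tries)) {
    cand <- target$init_fn()
    v <- target$eval(cand)
    if (is.finite(v[1])) { theta <- cand; lp <- v[1]; ll <- v[2]; break }
  }
  if (is.null(theta))
    stop("could not find a finite-posterior initial value after ",
         max_init_tries, " tries", call. = FALSE)

  log_sd <- rep(log(0.1), n_par)
  acc_count <- rep(0L, n_par)
  batch_n <- 0L; batch_i <- 0L
  # running moments of the full parameter vector for the adaptive joint
  # proposal (captures master-parameter/random-effect correlations)
  use_joint <- n_par >= 2
  jm_n <- 0; jm_mean <- numeric(n_par); jm_M2 <- matrix(0, n_par, n_par)
  jm_chol <- NULL
  jm_acc <- 0L; jm_tot <- 0L

  n_keep <- floor((n_iter - burn_in) / thin)
  draws <- matrix(NA_real_, n_keep, n_par)
  logliks <- numeric(n_keep)
  kept <- 0L

  for (it in seq_len(n_iter)) {
    adapting <- it <= burn_in
    z <- stats::rnorm(n_par)
    logu <- log(stats::runif(n_par))
    for (j in seq_len(n_par)) {
      prop <- theta
      prop[j] <- theta[j] + exp(log_sd[j]) * z[j]
      pv <- target$eval(prop)
      if (pv[1] - lp > logu[j]) {
        theta <- prop; lp <- pv[1]; ll <- pv[2]
        acc_count[j] <- acc_count[j] + 1L
      }
    }
    if (use_joint) {
      # Haario-style adaptive Metropolis: the empirical covariance keeps
      # adapting (with diminishing influence) for the whole run, and the
      # proposal mixes in a small fixed-scale component for robustness
      jm_n <- jm_n + 1
      dlt <- theta - jm_mean
      jm_mean <- jm_mean + dlt / jm_n
      jm_M2 <- jm_M2 + tcrossprod(dlt, theta - jm_mean)
      if (jm_n >= max(200, 2 * n_par) && jm_n %% adapt_batch == 0) {
        S <- jm_M2 / (jm_n - 1) * (2.38^2 / n_par) + diag(1e-10, n_par)
        jm_chol <- tryCatch(chol(S), error = function(e) NULL)
      }
      if (!is.null(jm_chol)) {
        prop <- if (stats::runif(1) < 0.95)
          theta + drop(stats::rnorm(n_par) %*% jm_chol)
        else theta + stats::rnorm(n_par, 0, 0.1 / sqrt(n_par))
        pv <- target$eval(prop)
        jm_tot <- jm_tot + 1L
        if (pv[1] - lp > log(stats::runif(1))) {
          theta <- prop; lp <- pv[1]; ll <- pv[2]; jm_acc <- jm_acc + 1L
        }
      }
    }
    batch_i <- batch_i + 1L
    if (adapting && batch_i == adapt_batch) {
      batch_n <- batch_n + 1L
      delta <- min(0.05, 1 / sqrt(batch_n))
      rate <- acc_count / adapt_batch
      log_sd <- log_sd + ifelse(rate > 0.44, delta, -delta)
      acc_count[] <- 0L; batch_i <- 0L
    } else if (batch_i == adapt_batch) {
      batch_i <- 0L; acc_count[] <- 0L
    }
    if (it > burn_in && (it - burn_in) %% thin == 0) {
      kept <- kept + 1L
      draws[kept, ] <- theta
      logliks[kept] <- ll
    }
  }
  list(draws = draws, logliks = logliks,
       joint_acc = if (jm_tot > 0) jm_acc / jm_tot else NA_real_)
}

#' Sample the posterior by adaptive Metropolis-within-Gibbs MCMC
#'
#' Runs several independent Markov chains of componentwise Gaussian
#' random-walk Metropolis updates whose step sizes adapt during burn-in
#' (batch acceptance-rate targeting of 0.44), plus a full-vector adaptive
#' Metropolis proposal whose covariance is learned during burn-in — the
#' master RAW parameters and the taxonomic effects are strongly correlated
#' a posteriori, and the joint move is what lets the chains traverse that
#' ridge. Identical seed, settings and data give identical draws.
#'
#' @param model A \code{\link{build_model}} object (or any list with
#'   elements \code{n_par}, \code{log_post}, and optionally
#'   \code{init_fn}, \code{par_names}, for sampling a generic target).
#' @param n_chains Number of chains (default 3).
#' @param n_iter Iterations per chain (default 15000).
#' @param burn_in Discarded initial iterations per chain (default 5000).
#' @param thin Keep one draw per \code{thin} post-burn-in iterations
#'   (default 10).
#' @param seed Integer RNG seed; required for reproducibility.
#' @return An object of class \code{mort_fit}: \code{draws} (array
#'   [kept iterations, chains, parameters] on the unconstrained scale),
#'   \code{logliks}, \code{rhat} (per parameter), \code{summaries}
#'   (natural-scale posterior summaries), \code{dic}/\code{pd} when the
#'   target exposes a likelihood, and the full settings record.
#' @export
run_mcmc <- function(model, n_chains = 3, n_iter = 15000, burn_in = 5000,
                     thin = 10, seed = 1) {
  stopifnot(n_chains >= 1, n_iter > burn_in, thin >= 1)
  target <- as_mcmc_target(model)
  set.seed(seed)
  chains <- lapply(seq_len(n_chains), function(ch)
    run_one_chain(target, n_iter, burn_in, thin))
  n_keep <- nrow(chains[[1]]$draws)
  draws <- array(NA_real_, c(n_keep, n_chains, target$n_par),
                 dimnames = list(NULL, NULL, target$par_names))
  logliks <- matrix(NA_real_, n_keep, n_chains)
  for (ch in seq_len(n_chains)) {
    draws[, ch, ] <- chains[[ch]]$draws
    logliks[, ch] <- chains[[ch]]$logliks
  }
  rhat <- if (n_chains >= 2 && n_keep >= 2) gelman_rubin(draws) else
    stats::setNames(rep(NA_real_, target$n_par), target$par_names)

  fit <- structure(list(
    spec = if (inherits(model, "mort_model")) model$spec else NULL,
    par_names = target$par_names,
    draws = draws, logliks = logliks, rhat = rhat,
    settings = list(n_chains = n_chains, n_iter = n_iter, burn_in = burn_in,
                    thin = thin, seed = seed),
    n_retained = n_keep * n_chains
  ), class = "mort_fit")

  if (inherits(model, "mort_model")) {
    nat <- natural_draws(model, fit)
    fit$summaries <- summarize_draws(nat, rhat_of = rhat_natural_names(model, rhat))
    d <- dic(fit, model)
    fit$dic <- d$dic; fit$pd <- d$pd; fit$pd_variance <- d$pd_variance
  } else {
    pooled <- apply(draws, 3, identity)
    fit$summaries <- summarize_draws(pooled, rhat_of = rhat)
  }
  fit
}

# flatten [iter, chain, par] to pooled [iter*chain, par]
pooled_draws <- function(fit) {
  d <- fit$draws
  matrix(aperm(d, c(1, 2, 3)), nrow = dim(d)[1] * dim(d)[2], ncol = dim(d)[3],
         dimnames = list(NULL, dimnames(d)[[3]]))
}

# natural-scale pooled draw matrix for a mort_model fit
natural_draws <- function(model, fit) {
  u <- pooled_draws(fit)
  out <- matrix(NA_real_, nrow(u), 0)
  add <- function(out, m) cbind(out, m)
  nat <- cbind(a = exp(u[, "log_a"]), b = 1 + exp(u[, "log_bm1"]),
               c = exp(u[, "log_c"]))
  out <- add(out, nat)
  for (lev in model$spec$active_levels) {
    e <- u[, model$lvl_eff_idx[[lev]], drop = FALSE]
    colnames(e) <- sprintf("eps[%s:%s]", lev, model$lvl_groups[[lev]])
    out <- add(out, e)
    tau <- exp(u[, model$tau_idx[[lev]], drop = FALSE])
    colnames(tau) <- sprintf("tau[%s]", lev)
    out <- add(out, tau)
  }
  h <- stats::plogis(u[, model$h_idx, drop = FALSE])
  h <- sweep(h, 2, 2 * model$data$datasets$h_rough, "*")
  colnames(h) <- sprintf("h[%s]", model$data$datasets$dataset_id)
  add(out, h)
}

rhat_natural_names <- function(model, rhat) {
  nm <- names(rhat)
  nm[nm == "log_a"] <- "a"; nm[nm == "log_bm1"] <- "b"; nm[nm == "log_c"] <- "c"
  nm <- sub("^log_tau\\[", "tau[", nm)
  nm <- sub("^logit_h\\[", "h[", nm)
  stats::setNames(as.numeric(rhat), nm)
}

summarize_draws <- function(mat, rhat_of = NULL) {
  qs <- t(apply(mat, 2, stats::quantile, probs = c(0.025, 0.5, 0.975), names = FALSE))
  out <- tibble(
    parameter = colnames(mat),
    mean = colMeans(mat),
    sd = apply(mat, 2, stats::sd),
    q2.5 = qs[, 1], median = qs[, 2], q97.5 = qs[, 3])
  out$rhat <- if (is.null(rhat_of)) NA_real_ else
    as.numeric(rhat_of[match(out$parameter, names(rhat_of))])
  out
}

#' @export
print.mort_fit <- function(x, ...) {
  cat("Posterior fit")
  if (!is.null(x$spec)) cat(" of", format(x$spec))
  cat(sprintf("\n  %d retained draws (%d chains); max Rhat = %.3f\n",
              x$n_retained, x$settings$n_chains, max(x$rhat, na.rm = TRUE)))
  if (!is.null(x$dic))
    cat(sprintf("  DIC = %.1f  pD = %.1f\n", x$dic, x$pd))
  print(utils::head(x$summaries, 10))
  if (nrow(x$summaries) > 10) cat("  ... and", nrow(x$summaries) - 10, "more parameters\n")
  invisible(x)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' The classic split-free multi-chain PSRF: with m chains of n draws,
#' within-chain variance W, between-chain variance B (n times the variance
#' of chain means), the pooled posterior-variance estimate is
#' \eqn{\hat V = (n-1)/n \, W + (1 + 1/m) B / n} and
#' \eqn{\hat R = \sqrt{\hat V / W}}. Values near 1 indicate that the chains
#' are mixing over a common distribution; the conventional convergence
#' criterion is \eqn{\hat R < 1.1}.
#'
#' @param draws Either a 3-d array [iterations, chains, parameters] or a
#'   matrix [iterations, chains] for a single parameter.
#' @return Named numeric vector of \eqn{\hat R}, one per parameter.
#' @export
gelman_rubin <- function(draws) {
  if (is.matrix(draws)) draws <- array(draws, c(nrow(draws), ncol(draws), 1))
  stopifnot(length(dim(draws)) == 3)
  m <- dim(draws)[2]; n <- dim(draws)[1]
  if (m < 2) stop("Gelman-Rubin diagnostic needs at least 2 chains", call. = FALSE)
  if (n < 2) stop("Gelman-Rubin diagnostic needs at least 2 draws per chain", call. = FALSE)
  out <- apply(draws, 3, function(x) {
    W <- mean(apply(x, 2, stats::var))
    B <- n * stats::var(colMeans(x))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + (1 + 1 / m) * B / n) / W)
  })
  stats::setNames(out, dimnames(draws)[[3]])
}

#' Deviance information criterion
#'
#' \eqn{\mathrm{DIC} = \bar D + p_D} with \eqn{\bar D} the posterior mean
#' deviance (deviance = -2 log likelihood). The default effective parameter
#' count is Spiegelhalter's \eqn{p_D = \bar D - D(\bar\theta)}, the mean
#' deviance minus the deviance at the posterior mean of the (unconstrained)
#' parameters; the variance-based alternative \eqn{p_D = \mathrm{var}(D)/2}
#' (the JAGS convention) is always reported alongside and used as a
#' fallback when the posterior-mean deviance is not finite.
#'
#' @param fit A \code{mort_fit} from \code{\link{run_mcmc}}.
#' @param model The \code{\link{build_model}} object the fit came from.
#' @param pd_method \code{"spiegelhalter"} (default) or \code{"variance"}.
#' @return List with \code{dic}, \code{pd}, \code{dbar}, and
#'   \code{pd_variance}.
#' @export
dic <- function(fit, model, pd_method = model$config$pd_method) {
  stopifnot(inherits(fit, "mort_fit"), inherits(model, "mort_model"))
  dev <- -2 * as.numeric(fit$logliks)
  dbar <- mean(dev)
  pd_var <- stats::var(dev) / 2
  theta_bar <- colMeans(pooled_draws(fit))
  dhat <- -2 * joint_log_lik(model, theta_bar)
  pd_spieg <- dbar - dhat
  pd <- if (identical(pd_method, "variance")) pd_var else pd_spieg
  if (!is.finite(pd)) {
    warning("deviance at the posterior mean is not finite; using variance-based pD",
            call. = FALSE)
    pd <- pd_var
  }
  list(dic = dbar + pd, pd = pd, dbar = dbar, pd_variance = pd_var)
}

#' Fit and rank candidate variance-component models by DIC
#'
#' Fits each candidate \code{\link{model_spec}} to the same data with
#' identical sampler settings and returns a table ranked by DIC (best =
#' lowest first). Failed fits are recorded with their error message rather
#' than dropped.
#'
#' @param data A \code{mort_data} collection.
#' @param specs List of \code{\link{model_spec}} (default: all 16).
#' @param config A \code{\link{natmort_config}}.
#' @param keep_fits Return the individual fits as an attribute?
#' @inheritParams run_mcmc
#' @return A tibble with columns \code{model, pD, DIC, max_rhat, status},
#'   sorted by increasing DIC.
#' @export
model_select <- function(data, specs = enumerate_specs(), config = NULL,
                         n_chains = 3, n_iter = 15000, burn_in = 5000,
                         thin = 10, seed = 1, keep_fits = FALSE) {
  stopifnot(inherits(data, "mort_data"))
  if (is.null(config)) config <- data$config
  fits <- vector("list", length(specs))
  rows <- lapply(seq_along(specs), function(i) {
    sp <- specs[[i]]
    res <- tryCatch({
      m <- build_model(data, sp, config)
      f <- run_mcmc(m, n_chains = n_chains, n_iter = n_iter,
                    burn_in = burn_in, thin = thin, seed = seed)
      if (keep_fits) fits[[i]] <<- f
      tibble(model = format(sp), pD = f$pd, DIC = f$dic,
             max_rhat = max(f$rhat, na.rm = TRUE), status = "ok")
    }, error = function(e)
      tibble(model = format(sp), pD = NA_real_, DIC = NA_real_,
             max_rhat = NA_real_, status = conditionMessage(e)))
    res
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(tab$DIC), ]
  if (keep_fits) attr(tab, "fits") <- fits
  tab
}

#' Export posterior draws as a long-format data frame
#'
#' Natural-scale draws, one row per retained iteration per chain, with
#' \code{chain} and \code{iter} index columns; suitable for writing to
#' delimited text.
#'
#' @inheritParams dic
#' @export
as_draws_df <- function(fit, model) {
  stopifnot(inherits(fit, "mort_fit"))
  n_keep <- dim(fit$draws)[1]; n_chains <- dim(fit$draws)[2]
  idx <- tibble(chain = rep(seq_len(n_chains), each = n_keep),
                iter = rep(seq_len(n_keep), n_chains))
  mat <- if (inherits(model, "mort_model")) {
    nd <- natural_draws(model, fit)
    # natural_draws pools chain-major; rebuild index order to match
    nd
  } else pooled_draws(fit)
  cbind(idx[order(idx$chain, idx$iter), ], as.data.frame(mat))
}
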