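# resolve the taxonomy labels at 'level' and all shallower levels from a key
resolve_key <- function(data, level, key) {
  ds <- data$datasets
  if (level == "master") return(list())
  key <- as.list(key)
  if (is.null(key[["dataset"]]) && !is.null(key[["dataset_id"]]))
    key[["dataset"]] <- key[["dataset_id"]]
  if (is.null(key[["study"]]) && !is.null(key[["study_id"]]))
    key[["study"]] <- key[["study_id"]]
  if (length(key) == 1L && is.null(names(key))) key <- stats::setNames(key, level)
  label <- key[[level]]
  if (is.null(label)) stop("key must supply a '", level, "' label", call. = FALSE)
  col <- c(subfamily = "subfamily", species = "species",
           study = "study_id", dataset = "dataset_id")
  hit <- ds[ds[[col[[level]]]] == label, ]
  if (nrow(hit) == 0L)
    stop("unknown ", level, " '", label, "': not present in the fitted taxonomy",
         call. = FALSE)
  depth <- match(level, LEVEL_NAMES)
  out <- list()
  for (lev in LEVEL_NAMES[seq_len(depth)]) out[[lev]] <- hit[[col[[lev]]]][1]
  out
}

# per-draw log psi at a taxonomic level, with lognormal bias correction for
# active levels deeper than it
draw_log_psi_at_level <- function(model, u, level, key) {
  n <- nrow(u)
  log_psi <- numeric(n)
  active <- model$spec$active_levels
  depth <- if (level == "master") 0L else match(level, LEVEL_NAMES)
  labels <- resolve_key(model$data, level, key)
  for (lev in active) {
    lev_depth <- match(lev, LEVEL_NAMES)
    if (lev_depth <= depth) {
      g <- match(labels[[lev]], model$lvl_groups[[lev]])
      log_psi <- log_psi + u[, model$lvl_eff_idx[[lev]][g]]
    } else {
      tau <- exp(u[, model$tau_idx[[lev]]])
      log_psi <- log_psi + 0.5 / tau        # lognormal bias correction
    }
  }
  log_psi
}

curve_summaries <- function(u, log_psi, ages, level, key_label) {
  a <- exp(u[, "log_a"]); b <- 1 + exp(u[, "log_bm1"]); cc <- exp(u[, "log_c"])
  psi <- exp(log_psi)
  out <- lapply(ages, function(t) {
    if (t > 0) {
      at <- a * t
      H <- at^b + at^(1 / b) + cc * t
      lam <- psi * (a * b * at^(b - 1) + (a / b) * at^(1 / b - 1) + cc)
    } else {
      H <- 0; lam <- rep(NA_real_, length(a))
    }
    S <- exp(-psi * H)
    qs <- stats::quantile(S, c(0.025, 0.975), names = FALSE)
    ql <- if (t > 0) stats::quantile(lam, c(0.025, 0.975), names = FALSE) else c(NA, NA)
    c(S_mean = mean(S), S_lo = qs[1], S_hi = qs[2],
      hazard_mean = if (t > 0) mean(lam) else NA_real_,
      hazard_lo = ql[1], hazard_hi = ql[2])
  })
  m <- do.call(rbind, out)
  tibble(level = level, key = key_label, age = ages,
         S_mean = m[, 1], S_lo = m[, 2], S_hi = m[, 3],
         hazard_mean = m[, 4], hazard_lo = m[, 5], hazard_hi = m[, 6])
}

#' Posterior survival and hazard curves at a taxonomic level
#'
#' Computes per-age posterior summaries (mean and 95\% credible bounds) of
#' the survival function and hazard rate at a chosen level of the model
#' hierarchy. For levels above the deepest active level, each draw's
#' multiplier receives the lognormal bias correction
#' \eqn{\psi = \exp(\sum \epsilon_k + 0.5 \sum_j \tau_j^{-1})} over the
#' omitted deeper levels, so the curve is the real-scale expectation over
#' the unobserved deeper effects. At the master level all effects are
#' integrated out this way.
#'
#' @param fit A \code{mort_fit} from \code{\link{run_mcmc}}.
#' @param model The fitted \code{\link{build_model}} object.
#' @param level One of \code{"master"}, \code{"subfamily"},
#'   \code{"species"}, \code{"study"}, \code{"dataset"}; must be the master
#'   level or an active level of the fitted spec.
#' @param key Label of the group at \code{level} (ignored for master);
#'   either a bare string or a named list.
#' @param ages Ages (years) at which to evaluate; default 0 to 40 by 0.25.
#' @return A tibble with columns \code{level, key, age, S_mean, S_lo, S_hi,
#'   hazard_mean, hazard_lo, hazard_hi} (hazard is \code{NA} at age 0 where
#'   it diverges).
#' @export
curve_at_level <- function(fit, model, level = "master", key = NULL,
                           ages = seq(0, 40, by = 0.25)) {
  stopifnot(inherits(fit, "mort_fit"), inherits(model, "mort_model"))
  level <- match.arg(level, c("master", LEVEL_NAMES))
  if (level != "master" && !(level %in% model$spec$active_levels))
    stop("level '", level, "' is not active in the fitted model spec", call. = FALSE)
  u <- pooled_draws(fit)
  log_psi <- draw_log_psi_at_level(model, u, level, key)
  key_label <- if (level == "master") "master" else as.character(resolve_key(model$data, level, key)[[level]])
  curve_summaries(u, log_psi, ages, level, key_label)
}

#' Prior survival/hazard distribution for a population without data
#'
#' Constructs the model-implied prior for a new dataset of an already
#' fitted species: the new dataset contributes no likelihood, so its
#' effects at levels deeper than species are unobserved and are simulated
#' from their fitted level distributions, one draw of
#' \eqn{\epsilon \sim N(0, \tau_k^{-1})} per retained MCMC draw. This
#' widens the credible intervals relative to the species-level curve,
#' which is exactly the extra uncertainty a data-free population carries.
#'
#' Two equivalent routes are offered: \code{method = "simulate"} (default)
#' post-hoc simulation as above, and \code{method = "refit"}, which appends
#' an all-missing dataset to the data and reruns the MCMC (the new
#' dataset's effect is then sampled as a model parameter with no
#' likelihood contribution). The refit route also takes the new dataset's
#' rough harvest rate into account; with no data either route leaves the
#' posterior of all other parameters unchanged up to Monte-Carlo error.
#'
#' @inheritParams curve_at_level
#' @param species Species label (must exist in the fitted taxonomy).
#' @param h_rough Rough harvest rate for the new population (default 0.001,
#'   an arbitrarily small value for an unharvested population; only used by
#'   the refit route, since harvest does not enter the natural-mortality
#'   curves).
#' @param method \code{"simulate"} or \code{"refit"}.
#' @param seed RNG seed for the simulated effects (simulate route) or the
#'   refit sampler.
#' @param ... Passed to \code{\link{run_mcmc}} for the refit route.
#' @return A curve tibble as in \code{\link{curve_at_level}}, with
#'   \code{level = "prediction"}.
#' @export
predict_prior_population <- function(fit, model, species, h_rough = 0.001,
                                     method = c("simulate", "refit"),
                                     ages = seq(0, 40, by = 0.25), seed = 1, ...) {
  stopifnot(inherits(fit, "mort_fit"), inherits(model, "mort_model"))
  method <- match.arg(method)
  labels <- resolve_key(model$data, "species", species)  # errors if unknown

  if (method == "simulate") {
    u <- pooled_draws(fit)
    log_psi <- draw_log_psi_at_level_predictive(model, u, labels, seed)
    return(curve_summaries(u, log_psi, ages, "prediction", labels$species))
  }

  # refit route: append an all-missing dataset under this species
  data2 <- model$data
  new_id <- make.unique(c(data2$datasets$dataset_id, "new_population"))[nrow(data2$datasets) + 1]
  new_study <- make.unique(c(data2$datasets$study_id, "new_study"))[nrow(data2$datasets) + 1]
  data2$datasets <- rbind(data2$datasets,
                          tibble(dataset_id = new_id, study_id = new_study,
                                 species = labels$species, subfamily = labels$subfamily,
                                 h_rough = h_rough))
  model2 <- build_model(data2, model$spec, model$config)
  fit2 <- run_mcmc(model2, seed = seed, ...)
  out <- curve_at_level(fit2, model2, "dataset", new_id, ages = ages)
  out$level <- "prediction"
  out$key <- labels$species
  out
}

# predictive log psi: species-level retained effects plus simulated deeper
# effects (one per draw) from their fitted precisions
draw_log_psi_at_level_predictive <- function(model, u, labels, seed) {
  n <- nrow(u)
  depth <- match("species", LEVEL_NAMES)
  log_psi <- numeric(n)
  set.seed(seed)
  for (lev in model$spec$active_levels) {
    if (match(lev, LEVEL_NAMES) <= depth) {
      g <- match(labels[[lev]], model$lvl_groups[[lev]])
      log_psi <- log_psi + u[, model$lvl_eff_idx[[lev]][g]]
    } else {
      tau <- exp(u[, model$tau_idx[[lev]]])
      log_psi <- log_psi + stats::rnorm(n, 0, 1 / sqrt(tau))
    }
  }
  log_psi
}
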