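#' Configuration defaults for the hierarchical mortality model
#'
#' Collects every tunable constant in one place. Defaults:
#' \itemize{
#'   \item \code{max_age = 60}: age at which open-ended ranges ("5+") are
#'     closed; chosen so that survival past it is negligible
#'     (\eqn{S(60) < 10^{-6}}) for plausible large-mammal hazards.
#'   \item \code{default_logit_sd = 1.0}: conservative logit-scale SD
#'     assigned to estimates with no precision information.
#'   \item \code{range_weights_use_harvest = TRUE}: age-range and
#'     catch-at-age weights reflect total (harvest-adjusted) mortality,
#'     since the standing age structure of a harvested population does.
#'   \item \code{first_catch_age = 1}: age of the first catch-count cell.
#'   \item \code{alpha = 1, beta = 0.1, init_tau = 0.1} per taxonomic level:
#'     Gamma(alpha, beta) hyperpriors (rate parameterisation) on each
#'     variance-component precision \eqn{\tau_k}, weakly informative so as
#'     to promote shrinkage while letting data dominate; \code{init_tau} is
#'     the sampler's initial value.
#'   \item master-parameter priors: weakly informative normals on the
#'     unconstrained scale, log a ~ N(log 0.1, 1.5^2),
#'     log(b - 1) ~ N(0, 1.5^2), log c ~ N(log 0.01, 1.5^2), wide enough to
#'     cover mammalian-plausible bathtub hazards.
#' }
#'
#' @param ... Named overrides of any default.
#' @return A named list of class \code{natmort_config}.
#' @export
natmort_config <- function(...) {
  cfg <- list(
    max_age = 60,
    default_logit_sd = 1.0,
    range_weights_use_harvest = TRUE,
    first_catch_age = 1,
    tau_alpha = c(subfamily = 1, species = 1, study = 1, dataset = 1),
    tau_beta = c(subfamily = 0.1, species = 0.1, study = 0.1, dataset = 0.1),
    init_tau = c(subfamily = 0.1, species = 0.1, study = 0.1, dataset = 0.1),
    master_prior_mean = c(log_a = log(0.1), log_bm1 = 0, log_c = log(0.01)),
    master_prior_sd = c(log_a = 1.5, log_bm1 = 1.5, log_c = 1.5),
    pd_method = "spiegelhalter"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config option(s): ",
                            paste(unknown, collapse = ", "), call. = FALSE)
  cfg[names(dots)] <- dots
  structure(cfg, class = "natmort_config")
}

#' @export
print.natmort_config <- function(x, ...) {
  cat("natmort configuration:\n")
  for (nm in names(x)) {
    v <- unlist(x[[nm]])
    vf <- if (is.numeric(v)) signif(v, 6) else v
    cat(sprintf("  %-26s %s\n", nm,
                if (is.null(names(v))) paste(vf, collapse = ", ")
                else paste(names(v), vf, sep = "=", collapse = ", ")))
  }
  invisible(x)
}

#' Variance-component model specification
#'
#' A model is identified by which taxonomic levels carry variance components
#' on the log hazard multipliers; the master RAW parameters are always
#' present. The 16 candidate models are all subsets of
#' \{subfamily, species, study, dataset\}.
#'
#' @param active_levels Character vector, a subset of
#'   \code{c("subfamily", "species", "study", "dataset")}; empty for the
#'   master-only model.
#' @return An object of class \code{model_spec}.
#' @examples
#' model_spec(c("species", "dataset"))
#' @export
model_spec <- function(active_levels = character(0)) {
  active_levels <- as.character(active_levels)
  bad <- setdiff(active_levels, LEVEL_NAMES)
  if (length(bad)) stop("unknown taxonomic level(s): ", paste(bad, collapse = ", "),
                        "; levels are ", paste(LEVEL_NAMES, collapse = ", "), call. = FALSE)
  if (anyDuplicated(active_levels)) stop("duplicated levels in spec", call. = FALSE)
  # canonical order: shallow to deep
  active_levels <- LEVEL_NAMES[LEVEL_NAMES %in% active_levels]
  structure(list(active_levels = active_levels), class = "model_spec")
}

#' @export
format.model_spec <- function(x, ...) {
  paste(c("~master", x$active_levels), collapse = " + ")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Model spec:", format(x), "\n")
  invisible(x)
}

#' Enumerate all candidate variance-component models
#'
#' All \eqn{2^4 = 16} subsets of \{subfamily, species, study, dataset\},
#' in deterministic order: by subset size, then lexically within size.
#'
#' @return A list of 16 \code{\link{model_spec}} objects.
#' @export
enumerate_specs <- function() {
  subsets <- list(character(0))
  for (k in 1:4) {
    combos <- utils::combn(sort(LEVEL_NAMES), k, simplify = FALSE)
    subsets <- c(subsets, combos)
  }
  lapply(subsets, model_spec)
}

#' Log prior density of the taxonomic random effects
#'
#' Each level-k effect is centred normal, \eqn{\epsilon \sim N(0, \tau_k^{-1})};
#' the density sums over all groups of every active level.
#'
#' @param effects Named list: one numeric vector of group effects per active
#'   level.
#' @param precisions Named numeric vector of level precisions \eqn{\tau_k}.
#' @param spec A \code{\link{model_spec}}; levels present in \code{effects}
#'   must match its active levels.
#' @export
log_multiplier_prior <- function(effects, precisions, spec) {
  stopifnot(inherits(spec, "model_spec"))
  extra <- setdiff(names(effects), spec$active_levels)
  if (length(extra)) stop("effects supplied for inactive level(s): ",
                          paste(extra, collapse = ", "), call. = FALSE)
  missing <- setdiff(spec$active_levels, names(effects))
  if (length(missing)) stop("missing effects for active level(s): ",
                            paste(missing, collapse = ", "), call. = FALSE)
  total <- 0
  for (lev in spec$active_levels) {
    tau <- precisions[[lev]]
    if (is.null(tau) || !is.finite(tau) || tau <= 0)
      stop("positive precision required for level ", lev, call. = FALSE)
    total <- total + sum(stats::dnorm(effects[[lev]], 0, 1 / sqrt(tau), log = TRUE))
  }
  total
}

#' Log hyperprior density of the variance-component precisions
#'
#' Conjugate Gamma(\eqn{\alpha_k}, \eqn{\beta_k}) priors (rate
#' parameterisation) on each active level's precision.
#'
#' @inheritParams log_multiplier_prior
#' @param config A \code{\link{natmort_config}} supplying
#'   \code{tau_alpha}/\code{tau_beta} per level.
#' @export
precision_hyperprior <- function(precisions, spec, config = natmort_config()) {
  stopifnot(inherits(spec, "model_spec"))
  total <- 0
  for (lev in spec$active_levels) {
    tau <- precisions[[lev]]
    if (is.null(tau) || !is.finite(tau) || tau <= 0)
      stop("positive precision required for level ", lev, call. = FALSE)
    total <- total + stats::dgamma(tau, shape = config$tau_alpha[[lev]],
                                   rate = config$tau_beta[[lev]], log = TRUE)
  }
  total
}

#' Log prior density of a dataset's harvest rate
#'
#' Diffuse uniform prior \eqn{h_d \sim \mathrm{Uniform}(0, 2\tilde h_d)},
#' where \eqn{\tilde h_d} is the user-supplied rough harvest rate
#' (arbitrarily small, e.g. 0.001, for unharvested populations).
#'
#' @param h Harvest rate value at which to evaluate the prior.
#' @param h_rough Rough harvest-rate estimate \eqn{\tilde h_d} in (0, 0.5].
#' @return Log density: \code{-log(2 h_rough)} inside the support,
#'   \code{-Inf} outside.
#' @export
harvest_prior <- function(h, h_rough) {
  stopifnot(length(h) == 1L, length(h_rough) == 1L)
  if (is.na(h_rough) || h_rough <= 0 || h_rough > 0.5)
    stop("'h_rough' must lie in (0, 0.5]; rescale the rough harvest rate", call. = FALSE)
  if (is.na(h) || h <= 0 || h >= 2 * h_rough) return(-Inf)
  -log(2 * h_rough)
}

#' Assemble a dataset's hazard multiplier from fitted effects
#'
#' \eqn{\log \psi_d = \sum_{k \in K_d} \epsilon_k}: the sum, over the active
#' levels of the model spec, of the effect of the group the dataset belongs
#' to at that level. With no active levels \eqn{\psi_d = 1} (master-only
#' model).
#'
#' @param key Named character vector or list with entries
#'   \code{subfamily, species, study, dataset} locating the dataset in the
#'   taxonomy.
#' @param spec A \code{\link{model_spec}}.
#' @param effects Named list: per active level, a named numeric vector of
#'   group effects (names are group labels at that level).
#' @return A \code{\link{hazard_multiplier}}.
#' @export
assemble_multiplier <- function(key, spec, effects) {
  stopifnot(inherits(spec, "model_spec"))
  key <- as.list(key)
  # dataset keys use 'dataset'/'dataset_id' and 'study'/'study_id'
  # interchangeably (exact [[ matching: $ would partial-match dataset_id)
  if (is.null(key[["dataset"]]) && !is.null(key[["dataset_id"]]))
    key[["dataset"]] <- key[["dataset_id"]]
  if (is.null(key[["study"]]) && !is.null(key[["study_id"]]))
    key[["study"]] <- key[["study_id"]]
  comps <- numeric(0)
  for (lev in spec$active_levels) {
    grp <- key[[lev]]
    if (is.null(grp) || is.null(effects[[lev]]) || !(grp %in% names(effects[[lev]])))
      stop("no fitted effect for level '", lev, "' group '",
           if (is.null(grp)) "?" else grp, "'", call. = FALSE)
    comps[lev] <- effects[[lev]][[grp]]
  }
  hazard_multiplier(comps)
}
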