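#' Build a nested taxonomy table for simulation
#'
#' Assigns species round-robin to subfamilies, studies to species and
#' datasets to studies, giving a balanced nested taxonomy of the kind the
#' hierarchical model assumes. Half the datasets (by default) are marked as
#' harvested with a rough harvest rate of 0.1; the rest get the
#' conventional arbitrarily small rough rate 0.001 of an unharvested
#' population.
#'
#' @param n_subfamilies,n_species,n_studies,n_datasets Taxonomy sizes
#'   (must be weakly increasing with depth).
#' @param harvested_fraction Fraction of datasets subject to harvest.
#' @param h_rough_harvested,h_rough_unharvested Rough harvest rates
#'   assigned to harvested / unharvested datasets.
#' @return A data frame with one row per dataset: \code{dataset_id,
#'   study_id, species, subfamily, h_rough, h_true}.
#' @export
simulate_taxonomy <- function(n_subfamilies = 2, n_species = 4, n_studies = 6,
                              n_datasets = 8, harvested_fraction = 0.5,
                              h_rough_harvested = 0.1,
                              h_rough_unharvested = 0.001) {
  stopifnot(n_subfamilies <= n_species, n_species <= n_studies,
            n_studies <= n_datasets)
  species_subfam <- rep(seq_len(n_subfamilies), length.out = n_species)
  study_species <- rep(seq_len(n_species), length.out = n_studies)
  ds_study <- rep(seq_len(n_studies), length.out = n_datasets)
  harvested <- seq_len(n_datasets) <= round(harvested_fraction * n_datasets)
  h_rough <- ifelse(harvested, h_rough_harvested, h_rough_unharvested)
  data.frame(
    dataset_id = sprintf("d%02d", seq_len(n_datasets)),
    study_id = sprintf("st%02d", ds_study),
    species = sprintf("sp%02d", study_species[ds_study]),
    subfamily = sprintf("sf%02d", species_subfam[study_species[ds_study]]),
    h_rough = h_rough,
    h_true = h_rough,
    stringsAsFactors = FALSE)
}

#' Simulate a mortality-data collection from known truth
#'
#' Inverts the full generative model: draws taxonomic effects
#' \eqn{\epsilon \sim N(0, \mathrm{sd}_k^2)} per group at each level with a
#' positive SD, forms each dataset's hazard multiplier
#' \eqn{\psi_d = \exp(\sum \epsilon)}, computes true harvest-adjusted
#' survival quantities under the RAW baseline, and emits the three record
#' types: age-specific estimates and age-range estimates with logit-normal
#' observation noise (the reported standard-error column encodes the
#' noise precision exactly under the delta-method rule), and catch-at-age
#' cohorts drawn multinomially with Poisson-distributed totals. Returns the
#' collection together with a ground-truth record for recovery tests.
#'
#' @param true_params A \code{\link{raw_params}} object, the master hazard.
#' @param taxonomy Data frame as from \code{\link{simulate_taxonomy}}
#'   (columns \code{dataset_id, study_id, species, subfamily, h_rough}, and
#'   optionally \code{h_true}, defaulting to \code{h_rough}).
#' @param level_sd Named numeric vector of true effect SDs per taxonomic
#'   level; levels absent or 0 carry no effects.
#' @param obs_logit_sd Logit-scale SD of survival-estimate observation
#'   noise (default 0.2); 0 gives noise-free estimates.
#' @param age_set Candidate ages for age-specific estimates (default 0:9,
#'   the data-rich juvenile and adult ages).
#' @param age_prob Inclusion probability of each candidate age per dataset
#'   (default 0.75, leaving realistic sparse gaps).
#' @param range_t1,range_t2 Age range reported as a single range estimate
#'   per dataset (default ages 1-4, a typical "subadult" figure).
#' @param catch_n_ages Number of age classes in simulated catch vectors
#'   (default 15, starting at age 1).
#' @param catch_mean_total Poisson mean of a cohort's total catch
#'   (default 200, a typical harvest-record size).
#' @param catch_cohorts Catch cohorts per harvested dataset (default 1;
#'   unharvested datasets emit no catch data).
#' @param config A \code{\link{natmort_config}}.
#' @param seed Integer seed; identical seeds give identical collections.
#' @return A list of class \code{mort_sim}: \code{data} (a
#'   \code{mort_data}), and \code{truth} (true parameters, per-group
#'   effects, per-dataset multipliers and harvest rates, and the settings).
#' @export
generate_collection <- function(true_params, taxonomy = simulate_taxonomy(),
                                level_sd = c(species = 0.2, dataset = 0.2),
                                obs_logit_sd = 0.2,
                                age_set = 0:9, age_prob = 0.75,
                                range_t1 = 1, range_t2 = 4,
                                catch_n_ages = 15, catch_mean_total = 200,
                                catch_cohorts = 1,
                                config = natmort_config(), seed = 1) {
  true_params <- as_raw_params(true_params)
  stopifnot(is.data.frame(taxonomy))
  if (any(range_t1 > range_t2)) stop("impossible mix: range_t1 > range_t2", call. = FALSE)
  if (any(level_sd < 0)) stop("level SDs must be non-negative", call. = FALSE)
  if (is.null(taxonomy$h_true)) taxonomy$h_true <- taxonomy$h_rough
  set.seed(seed)

  level_col <- c(subfamily = "subfamily", species = "species",
                 study = "study_id", dataset = "dataset_id")
  active <- names(level_sd)[level_sd > 0]
  effects <- list()
  for (lev in active) {
    groups <- sort(unique(taxonomy[[level_col[[lev]]]]))
    effects[[lev]] <- stats::setNames(stats::rnorm(length(groups), 0, level_sd[[lev]]),
                                      groups)
  }
  log_psi <- numeric(nrow(taxonomy))
  for (lev in active)
    log_psi <- log_psi + effects[[lev]][taxonomy[[level_col[[lev]]]]]
  psi <- stats::setNames(exp(log_psi), taxonomy$dataset_id)

  noisy <- function(truth) {
    y <- stats::qlogis(truth) + stats::rnorm(length(truth), 0, obs_logit_sd)
    est <- stats::plogis(y)
    list(estimate = est,
         se = est * (1 - est) * max(obs_logit_sd, 1e-6))  # encodes tau exactly
  }

  rows <- list()
  for (d in seq_len(nrow(taxonomy))) {
    tx <- taxonomy[d, ]
    mult <- psi[[d]]
    h <- tx$h_true
    base <- data.frame(dataset_id = tx$dataset_id, study_id = tx$study_id,
                       species = tx$species, subfamily = tx$subfamily,
                       h_rough = tx$h_rough, stringsAsFactors = FALSE)
    ages <- age_set[stats::runif(length(age_set)) < age_prob]
    if (length(ages)) {
      truth <- harvest_adjusted_annual_survival(true_params, ages, h = h, mult = mult)
      ob <- noisy(truth)
      rows[[length(rows) + 1L]] <- cbind(base, type = "age", age = ages,
                                         t1 = NA, t2 = NA, cohort = NA, count = NA,
                                         estimate = ob$estimate, se = ob$se,
                                         ci_lo = NA, ci_hi = NA, ci_level = NA, n = NA)
    }
    truth_r <- range_survival(true_params, range_t1, range_t2, h = h, mult = mult,
                              use_harvest = config$range_weights_use_harvest)
    ob <- noisy(truth_r)
    rows[[length(rows) + 1L]] <- cbind(base, type = "range", age = NA,
                                       t1 = range_t1, t2 = range_t2,
                                       cohort = NA, count = NA,
                                       estimate = ob$estimate, se = ob$se,
                                       ci_lo = NA, ci_hi = NA, ci_level = NA, n = NA)
    if (tx$h_rough >= 0.01 && catch_cohorts > 0) {   # harvested datasets only
      p <- catch_cell_probs(true_params, catch_n_ages, h = h, mult = mult,
                            first_age = config$first_catch_age,
                            use_harvest = config$range_weights_use_harvest)
      for (co in seq_len(catch_cohorts)) {
        total <- stats::rpois(1, catch_mean_total)
        if (total == 0) next
        counts <- as.integer(stats::rmultinom(1, total, p))
        rows[[length(rows) + 1L]] <- cbind(
          base, type = "catch",
          age = config$first_catch_age + seq_len(catch_n_ages) - 1,
          t1 = NA, t2 = NA, cohort = sprintf("c%d", co), count = counts,
          estimate = NA, se = NA, ci_lo = NA, ci_hi = NA, ci_level = NA, n = NA)
      }
    }
  }
  df <- do.call(rbind, rows)
  structure(list(
    data = as_mort_data(df, config = config),
    truth = list(params = true_params, effects = effects, psi = psi,
                 h = stats::setNames(taxonomy$h_true, taxonomy$dataset_id),
                 level_sd = level_sd, obs_logit_sd = obs_logit_sd, seed = seed)
  ), class = "mort_sim")
}

#' @export
print.mort_sim <- function(x, ...) {
  cat("Synthetic mortality collection (seed", x$truth$seed, ")\n")
  print(x$data)
  invisible(x)
}

#' Packaged phocid-like synthetic fixture
#'
#' A small deterministic synthetic collection shaped like a scaled-down
#' multi-species seal meta-analysis: 2 subfamilies, 4 species, 6 studies,
#' 8 datasets, with all three record types and effects at all four
#' taxonomic levels. Used throughout the test suite; the ground truth is
#' returned alongside the data.
#'
#' @param seed Seed of the deterministic fixture (default 42).
#' @return A \code{mort_sim} list (see \code{\link{generate_collection}}).
#' @export
phocid_fixture <- function(seed = 42) {
  generate_collection(
    true_params = raw_params(0.054, 2.6, 0.006),
    taxonomy = simulate_taxonomy(2, 4, 6, 8),
    level_sd = c(subfamily = 0.1, species = 0.2, study = 0.1, dataset = 0.2),
    seed = seed)
}
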