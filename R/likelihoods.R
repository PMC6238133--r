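#' Logit-scale precision from a reported standard error
#'
#' Delta-method conversion of a probability-scale standard error to a
#' precision (inverse variance) on the logit scale:
#' \deqn{\tau = \tilde\phi^2 (1 - \tilde\phi)^2 / \mathrm{SE}^2.}
#'
#' @param estimate Reported survival probability, strictly inside (0, 1).
#' @param se Reported standard error on the probability scale, positive.
#' @return The logit-scale precision \eqn{\tau > 0}.
#' @examples
#' logit_precision_from_se(0.8, 0.05)  # 10.24
#' @export
logit_precision_from_se <- function(estimate, se) {
  stopifnot(is.numeric(estimate), is.numeric(se))
  if (any(estimate <= 0 | estimate >= 1))
    stop("'estimate' must lie strictly inside (0, 1); truncate boundary values first",
         call. = FALSE)
  if (any(se <= 0)) stop("'se' must be positive", call. = FALSE)
  estimate^2 * (1 - estimate)^2 / se^2
}

#' Logit-scale precision from whatever precision information is available
#'
#' Literature survival estimates come with heterogeneous precision
#' information. This resolves a single datum to a logit-scale precision
#' \eqn{\tau} by the first applicable rule:
#' \itemize{
#'   \item a standard error: delta method
#'     (\code{\link{logit_precision_from_se}});
#'   \item a confidence interval: \code{SE = (hi - lo) / (2 z)} with
#'     \code{z} the two-sided normal quantile for the stated level (interval
#'     assumed symmetric on the probability scale), then the delta method;
#'   \item a sample size n: binomial \code{SE = sqrt(estimate (1 - estimate) / n)},
#'     then the delta method;
#'   \item nothing: a conservative default, a logit-scale standard deviation
#'     of \code{default_logit_sd} (so \eqn{\tau} = \code{default_logit_sd^-2}).
#' }
#'
#' @param estimate Reported survival probability in (0, 1).
#' @param se Optional probability-scale standard error.
#' @param ci_lo,ci_hi Optional confidence bounds (must bracket the estimate).
#' @param ci_level Confidence level of the interval (default 0.95).
#' @param n Optional sample size behind the estimate.
#' @param default_logit_sd Conservative logit-scale SD used when no
#'   precision information is available (default 1.0).
#' @return The precision \eqn{\tau > 0}.
#' @examples
#' precision_from_fallbacks(0.8, n = 100)                     # 16
#' precision_from_fallbacks(0.7, ci_lo = 0.6, ci_hi = 0.8)    # ~16.94
#' precision_from_fallbacks(0.7)                              # 1 (default SD 1)
#' @export
precision_from_fallbacks <- function(estimate, se = NA, ci_lo = NA, ci_hi = NA,
                                     ci_level = 0.95, n = NA,
                                     default_logit_sd = 1.0) {
  stopifnot(length(estimate) == 1L)
  if (is.na(estimate) || estimate <= 0 || estimate >= 1)
    stop("'estimate' must lie strictly inside (0, 1)", call. = FALSE)
  if (!is.na(se)) return(logit_precision_from_se(estimate, se))
  if (!is.na(ci_lo) && !is.na(ci_hi)) {
    if (is.na(ci_level) || ci_level <= 0 || ci_level >= 1)
      stop("'ci_level' must lie in (0, 1)", call. = FALSE)
    if (ci_lo >= ci_hi)
      stop("inconsistent confidence interval: lower bound >= upper bound", call. = FALSE)
    if (estimate < ci_lo || estimate > ci_hi)
      stop("inconsistent confidence interval: estimate outside the interval", call. = FALSE)
    z <- stats::qnorm(1 - (1 - ci_level) / 2)
    return(logit_precision_from_se(estimate, (ci_hi - ci_lo) / (2 * z)))
  }
  if (!is.na(n)) {
    if (n <= 0) stop("'n' must be positive", call. = FALSE)
    return(logit_precision_from_se(estimate, sqrt(estimate * (1 - estimate) / n)))
  }
  if (default_logit_sd <= 0) stop("'default_logit_sd' must be positive", call. = FALSE)
  1 / default_logit_sd^2
}

#' Harvest-adjusted annual survival
#'
#' Annual survival of a harvested population under a pulse-harvest model:
#' a fraction \eqn{h} of the animals alive in an age class is removed once
#' per annual cycle, so total annual survival is
#' \eqn{\phi_{t,d} = (1 - h_d)\, S_d(t+1)/S_d(t)}, natural annual survival
#' times the pulse survival \eqn{1 - h}.
#'
#' @inheritParams annual_survival
#' @param h Harvest rate in [0, 1); 0 for unharvested populations.
#' @export
harvest_adjusted_annual_survival <- function(params, t, h = 0, mult = NULL) {
  stopifnot(is.numeric(h), length(h) == 1L)
  if (is.na(h) || h < 0 || h >= 1) stop("harvest rate 'h' must lie in [0, 1)", call. = FALSE)
  (1 - h) * annual_survival(params, t, mult = mult)
}

#' Age weights for an age-range survival estimate
#'
#' A survival estimate reported over an age range \[t1, t2\] is matched to a
#' weighted average of age-specific annual survivals, weighting each age by
#' the expected relative number of individuals alive in it. With the t1
#' class as reference (weight \eqn{\propto} 1), the unnormalised weight at
#' age t is the cumulative product of the annual survivals
#' \eqn{\phi_{t_1}, \dots, \phi_{t-1}}; weights are then normalised to
#' sum to 1. By default (matching the standing age structure of a harvested
#' population) the cumulative products use harvest-adjusted annual survival.
#'
#' @inheritParams harvest_adjusted_annual_survival
#' @param t1,t2 Integer age range bounds, \code{t1 <= t2}. Open-ended ranges
#'   ("5+") should be closed at a large age before calling (see
#'   \code{max_age} in \code{\link{natmort_config}}).
#' @param use_harvest Logical; if \code{TRUE} (default) the weights use
#'   harvest-adjusted annual survival, otherwise natural annual survival.
#' @return Numeric vector of weights over ages \code{t1:t2}, summing to 1.
#' @export
range_weights <- function(params, t1, t2, h = 0, mult = NULL, use_harvest = TRUE) {
  stopifnot(length(t1) == 1L, length(t2) == 1L)
  if (t1 > t2) stop("'t1' must not exceed 't2'", call. = FALSE)
  ages <- seq.int(t1, t2)
  if (length(ages) == 1L) return(1)
  phi <- if (use_harvest)
    harvest_adjusted_annual_survival(params, ages[-length(ages)], h = h, mult = mult)
  else annual_survival(params, ages[-length(ages)], mult = mult)
  w <- c(1, cumprod(phi))
  w / sum(w)
}

#' Model survival over an age range
#'
#' The abundance-weighted average \eqn{\phi_{[t_1,t_2],d} = \sum_t \phi_{t,d}\,\pi_{t,d}}
#' of harvest-adjusted annual survivals over the range, with weights from
#' \code{\link{range_weights}}. This is the model quantity a reported
#' "subadult" or "adult" survival estimate is compared against.
#'
#' @inheritParams range_weights
#' @export
range_survival <- function(params, t1, t2, h = 0, mult = NULL, use_harvest = TRUE) {
  w <- range_weights(params, t1, t2, h = h, mult = mult, use_harvest = use_harvest)
  phi <- harvest_adjusted_annual_survival(params, seq.int(t1, t2), h = h, mult = mult)
  sum(w * phi)
}

# shared logit-normal observation density
logit_normal_loglik <- function(estimate, mean_prob, tau) {
  r <- stats::qlogis(estimate) - stats::qlogis(mean_prob)
  0.5 * log(tau / (2 * pi)) - 0.5 * tau * r^2
}

#' Log-likelihood of an age-specific survival estimate
#'
#' Logit-normal observation model: the logit of the reported estimate is
#' normal around the logit of the model's harvest-adjusted annual survival
#' with precision \eqn{\tau}.
#'
#' @inheritParams harvest_adjusted_annual_survival
#' @param estimate Reported annual survival probability in (0, 1).
#' @param age Integer age class of the estimate.
#' @param tau Resolved logit-scale precision of the estimate.
#' @export
age_specific_loglik <- function(estimate, age, tau, params, h = 0, mult = NULL) {
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  phi <- harvest_adjusted_annual_survival(params, age, h = h, mult = mult)
  logit_normal_loglik(estimate, phi, tau)
}

#' Log-likelihood of an age-range survival estimate
#'
#' As \code{\link{age_specific_loglik}} with the weighted range survival
#' \code{\link{range_survival}} as the observation-model mean.
#'
#' @inheritParams range_survival
#' @inheritParams age_specific_loglik
#' @export
age_range_loglik <- function(estimate, t1, t2, tau, params, h = 0, mult = NULL,
                             use_harvest = TRUE) {
  if (tau <= 0) stop("'tau' must be positive", call. = FALSE)
  phi <- range_survival(params, t1, t2, h = h, mult = mult, use_harvest = use_harvest)
  logit_normal_loglik(estimate, phi, tau)
}

#' Multinomial cell probabilities for catch-at-age data
#'
#' Under age- and time-constant harvest rates, the expected age composition
#' of a harvested cohort is proportional to the expected numbers alive at
#' each age, i.e. to cumulative products of (harvest-adjusted) annual
#' survival from the first harvested age class onward.
#'
#' @inheritParams range_weights
#' @param n_ages Number of age classes T in the count vector.
#' @param first_age Age of the first count cell (default 1).
#' @return Probability vector of length \code{n_ages} summing to 1.
#' @export
catch_cell_probs <- function(params, n_ages, h = 0, mult = NULL, first_age = 1,
                             use_harvest = TRUE) {
  stopifnot(n_ages >= 1)
  range_weights(params, first_age, first_age + n_ages - 1, h = h, mult = mult,
                use_harvest = use_harvest)
}

#' Multinomial log-likelihood of a cohort's catch-at-age counts
#'
#' \deqn{[C_1, \dots, C_T] \sim \mathrm{multinomial}(\textstyle\sum_t C_t;\;
#'   \pi_1, \dots, \pi_T)}
#' with cell probabilities from \code{\link{catch_cell_probs}}.
#'
#' @inheritParams catch_cell_probs
#' @param counts Non-negative integer vector of harvest counts by age, total
#'   greater than 0.
#' @export
catch_at_age_loglik <- function(counts, params, h = 0, mult = NULL, first_age = 1,
                                use_harvest = TRUE) {
  stopifnot(is.numeric(counts), length(counts) >= 1L)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("'counts' must be non-negative with a positive total", call. = FALSE)
  p <- catch_cell_probs(params, length(counts), h = h, mult = mult,
                        first_age = first_age, use_harvest = use_harvest)
  stats::dmultinom(counts, prob = p, log = TRUE)
}
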