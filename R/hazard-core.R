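#' Reduced additive Weibull (RAW) hazard parameters
#'
#' Constructs and validates the three master parameters of the reduced
#' additive Weibull hazard, a three-parameter family producing the U-shaped
#' ("bathtub") mortality curve typical of mammalian life history: high
#' juvenile mortality driven by the \eqn{(at)^{1/b}} term, a low adult
#' plateau near \eqn{c}, and a senescent increase driven by \eqn{(at)^b}.
#'
#' The survival function is
#' \deqn{S(t) = \exp\{-(at)^b - (at)^{1/b} - ct\}}
#' and the corresponding hazard (instantaneous death rate) is
#' \deqn{\lambda(t) = ab(at)^{b-1} + (a/b)(at)^{1/b-1} + c.}
#'
#' @param a Positive rate-like scalar (per year); together with \code{b} it
#'   sets the location and steepness of the juvenile and senescent arms.
#' @param b Shape scalar, strictly greater than 1.
#' @param c Non-negative age-independent baseline hazard (per year).
#' @return An object of class \code{raw_params}.
#' @examples
#' p <- raw_params(a = 0.054, b = 2.6, c = 0.006)
#' raw_survival(p, t = c(0, 1, 10))
#' @export
raw_params <- function(a, b, c) {
  ok <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  if (!ok(a) || a <= 0) stop("'a' must be a finite positive scalar", call. = FALSE)
  if (!ok(b) || b <= 1)  stop("'b' must be a finite scalar > 1", call. = FALSE)
  if (!ok(c) || c < 0)   stop("'c' must be a finite non-negative scalar", call. = FALSE)
  structure(list(a = a, b = b, c = c), class = "raw_params")
}

#' @export
print.raw_params <- function(x, ...) {
  cat(sprintf("RAW hazard parameters: a = %g, b = %g, c = %g\n", x$a, x$b, x$c))
  invisible(x)
}

as_raw_params <- function(x) {
  if (inherits(x, "raw_params")) return(x)
  if (is.numeric(x) && length(x) == 3L) return(raw_params(x[[1]], x[[2]], x[[3]]))
  stop("cannot interpret 'params' as RAW parameters", call. = FALSE)
}

#' Proportional-hazard multiplier
#'
#' A per-dataset hazard adjustment \eqn{\psi_d} assembled from additive
#' log-scale taxonomic components: \eqn{\log \psi_d = \sum_k \epsilon_k},
#' where \eqn{k} ranges over the active taxonomic levels (subfamily, species,
#' study, dataset) the dataset belongs to. Under proportional hazards the
#' dataset survival function is the baseline raised to \eqn{\psi_d}.
#'
#' @param log_components Named numeric vector of log-scale components
#'   \eqn{\epsilon_k} (names identify levels); may be empty (then
#'   \eqn{\psi = 1}).
#' @return An object of class \code{hazard_multiplier} with elements
#'   \code{psi} and \code{log_components}.
#' @examples
#' hazard_multiplier(c(species = 0.1, dataset = -0.3))$psi  # exp(-0.2)
#' @export
hazard_multiplier <- function(log_components = numeric(0)) {
  stopifnot(is.numeric(log_components))
  if (anyNA(log_components) || any(!is.finite(log_components)))
    stop("log components must be finite", call. = FALSE)
  structure(list(psi = exp(sum(log_components)),
                 log_components = log_components),
            class = "hazard_multiplier")
}

#' @export
print.hazard_multiplier <- function(x, ...) {
  cat(sprintf("Hazard multiplier psi = %g", x$psi))
  if (length(x$log_components))
    cat(" (", paste(names(x$log_components), round(x$log_components, 4),
                    sep = "=", collapse = ", "), ")", sep = "")
  cat("\n")
  invisible(x)
}

psi_of <- function(mult) {
  if (is.null(mult)) return(1)
  if (inherits(mult, "hazard_multiplier")) return(mult$psi)
  if (is.numeric(mult) && length(mult) == 1L && is.finite(mult) && mult > 0) return(mult)
  stop("'mult' must be a hazard_multiplier or a positive scalar psi", call. = FALSE)
}

# cumulative hazard H(t) = (at)^b + (at)^{1/b} + ct, vectorised over t
raw_cumhaz <- function(params, t) {
  p <- as_raw_params(params)
  at <- p$a * t
  at^p$b + at^(1 / p$b) + p$c * t
}

#' RAW survival function
#'
#' Probability of surviving to at least age \code{t} (the life-table
#' survivorship schedule l(x)), optionally under a proportional-hazard
#' multiplier: \eqn{S_d(t) = S(t)^{\psi_d}}. Computed on the log scale to
#' avoid underflow at old ages.
#'
#' @param params A \code{\link{raw_params}} object.
#' @param t Non-negative age(s) in years; vectorised.
#' @param mult Optional \code{\link{hazard_multiplier}} or positive scalar
#'   \eqn{\psi} (default 1, the baseline).
#' @return Survival probabilities in (0, 1]; \code{S(0) = 1}.
#' @export
raw_survival <- function(params, t, mult = NULL) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("age 't' must be non-negative", call. = FALSE)
  exp(-psi_of(mult) * raw_cumhaz(params, t))
}

#' RAW hazard function
#'
#' Instantaneous death rate \eqn{\lambda(t)} at age \code{t}, optionally
#' scaled by a proportional-hazard multiplier. The juvenile term
#' \eqn{(a/b)(at)^{1/b-1}} diverges as \eqn{t \to 0^+}, so age 0 is a domain
#' error rather than returning infinity silently.
#'
#' @inheritParams raw_survival
#' @param t Strictly positive age(s) in years; vectorised.
#' @return Hazard rates (per year), each strictly greater than \eqn{\psi c}.
#' @export
raw_hazard <- function(params, t, mult = NULL) {
  stopifnot(is.numeric(t))
  if (any(t <= 0)) stop("hazard is undefined at t <= 0 (juvenile term diverges)", call. = FALSE)
  p <- as_raw_params(params)
  at <- p$a * t
  psi_of(mult) * (p$a * p$b * at^(p$b - 1) + (p$a / p$b) * at^(1 / p$b - 1) + p$c)
}

#' Dataset-adjusted survival under proportional hazards
#'
#' \eqn{S_d(t) = S(t)^{\psi_d}}: multiplying the hazard by \eqn{\psi_d}
#' raises the baseline survival function to the power \eqn{\psi_d}.
#'
#' @inheritParams raw_survival
#' @param mult A \code{\link{hazard_multiplier}} or positive scalar.
#' @export
adjusted_survival <- function(params, mult, t) raw_survival(params, t, mult = mult)

#' Annual (conditional) survival probability
#'
#' The probability of surviving to age \eqn{t + 1} conditional on being alive
#' at age \eqn{t}: \eqn{\phi_t = S_d(t+1)/S_d(t)}. Age convention: t = 0 is
#' birth, so \code{annual_survival(p, 0)} is first-year ("yearling") survival.
#'
#' @inheritParams raw_survival
#' @param t Non-negative integer age(s); vectorised.
#' @return Probabilities in (0, 1).
#' @export
annual_survival <- function(params, t, mult = NULL) {
  stopifnot(is.numeric(t))
  if (any(t < 0)) stop("age 't' must be non-negative", call. = FALSE)
  psi <- psi_of(mult)
  exp(-psi * (raw_cumhaz(params, t + 1) - raw_cumhaz(params, t)))
}

#' Age-at-death density
#'
#' The density of the failure-time distribution,
#' \eqn{f_d(t) = \lambda_d(t)\,S_d(t)}. Integrates to 1 over \eqn{(0,\infty)}
#' whenever the hazard does not vanish asymptotically (a > 0 or c > 0).
#'
#' @inheritParams raw_hazard
#' @export
mortality_density <- function(params, t, mult = NULL) {
  raw_hazard(params, t, mult = mult) * raw_survival(params, t, mult = mult)
}

#' Lognormal bias-corrected multiplier at a higher taxonomic level
#'
#' When a model includes effects below the level being reported (e.g.
#' dataset effects below species), exponentiating only the retained
#' components understates the real-scale mean multiplier. The lognormal
#' correction adds half the omitted-level variance inside the exponential:
#' \deqn{\psi_{level} = \exp\{\textstyle\sum_k \epsilon_k + \tfrac12 \sum_j \tau_j^{-1}\},}
#' where the first sum runs over retained components and the second over the
#' precisions of the omitted deeper levels.
#'
#' @param log_components Numeric vector (possibly empty) of retained
#'   log-scale components.
#' @param omitted_variance Total variance \eqn{\sum_j \tau_j^{-1}} of the
#'   omitted deeper-level effects; non-negative scalar.
#' @return The bias-corrected multiplier \eqn{\psi} (scalar).
#' @examples
#' bias_corrected_multiplier(0.3, 0.2)  # exp(0.4)
#' @export
bias_corrected_multiplier <- function(log_components = numeric(0), omitted_variance = 0) {
  stopifnot(is.numeric(log_components), is.numeric(omitted_variance),
            length(omitted_variance) == 1L)
  if (!is.finite(omitted_variance) || omitted_variance < 0)
    stop("'omitted_variance' must be a finite non-negative scalar", call. = FALSE)
  exp(sum(log_components) + 0.5 * omitted_variance)
}
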