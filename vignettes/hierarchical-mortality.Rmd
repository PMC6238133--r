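---
title: "Hierarchical Bayesian estimation of age-specific natural mortality"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical Bayesian estimation of age-specific natural mortality}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(natmort)
```

## The problem

Age-specific natural mortality is a foundational life-history parameter for
population modelling, yet for long-lived, hard-to-study mammals (high-latitude
phocid seals are the motivating case) it is rarely estimated well from any
single study. What the literature offers instead is a scatter of heterogeneous
fragments: an annual survival estimate for one age class here, a single
"subadult" (ages 1–4) survival figure there, and historical harvest records
giving the age composition of killed animals — each with its own precision,
and each confounding natural with harvest mortality to a different degree.

`natmort` pools such fragments across datasets, studies, species and
subfamilies in one hierarchical Bayesian model. Sparse datasets borrow
strength from data-rich relatives ("Robin Hood" shrinkage), every estimate is
weighted by its precision, harvest mortality is separated from natural
mortality through explicit harvest-rate priors, and the fitted hierarchy can
be queried at any taxonomic level — including constructing a prior
distribution of survival for a population with *no* mortality data at all.

## The model

### Baseline hazard

All data types are tied to a common currency: the survival function
$S(t) = \Pr(T \ge t)$ (the life-table survivorship schedule $l(x)$) and the
hazard $\lambda(t) = f(t)/S(t)$. The baseline follows the three-parameter
reduced additive Weibull (RAW) family (Xie & Lai 1996), which produces the
U-shaped ("bathtub") hazard typical of mammalian life history:

$$S(t) = \exp\{-(at)^b - (at)^{1/b} - ct\}, \qquad
\lambda(t) = ab(at)^{b-1} + \tfrac{a}{b}(at)^{1/b-1} + c,$$

with $a > 0$ (per year), $b > 1$, $c \ge 0$ (per year). The
$(at)^{1/b}$ term drives high juvenile mortality (its hazard contribution
diverges as $t \to 0^+$, which is why `raw_hazard()` treats age 0 as a domain
error), $c$ sets the adult floor, and $(at)^b$ drives senescence. The hazard
is exactly the derivative of the cumulative hazard
$H(t) = (at)^b + (at)^{1/b} + ct$ — note the $a/b$ coefficient on the
juvenile term, which is what makes $S = \exp(-H)$ and $\lambda = H'$
mutually consistent; the test suite enforces
$|S(t) - \exp(-\int_0^t \lambda)| < 10^{-8}$ by adaptive quadrature.
Survival is always computed via $\exp(-\psi H(t))$ on the log scale, so it
does not underflow at old ages.

### Proportional hazards across the taxonomy

Modelling among-dataset variation directly on $(a, b, c)$ is numerically
unstable (multimodal posteriors), so variation enters proportionally:
$\lambda_{t,d} = \psi_d \lambda_t$, equivalently $S_d(t) = S(t)^{\psi_d}$.
The log multiplier decomposes additively over the taxonomy,

$$\log \psi_d = \sum_{k \in K_d} \epsilon_k, \qquad
K_d \subseteq \{\text{subfamily, species, study, dataset}\},$$

with $\epsilon_k \sim N(0, \tau_k^{-1})$ per group and conjugate
$\tau_k \sim \text{Gamma}(\alpha_k, \beta_k)$ hyperpriors. A *model
specification* is the subset of levels that carry variance components; the
16 possible subsets (including the master-only model) are enumerated by
`enumerate_specs()` and compared by DIC. The subfamily component captures
deep taxonomic signal, species captures life-history differences, and the
study/dataset components absorb phenotypic plasticity among populations and
methodological artifacts — which is precisely what lets the taxonomic
components be interpreted.

Because $\psi$ enters nonlinearly, reporting survival at a level *above* the
deepest fitted level requires the lognormal bias correction: the real-scale
mean multiplier at, say, the species level under a model with dataset effects
is $\psi_{\text{species}} = \exp(\epsilon_{\text{species}} +
\tfrac12 \tau_{\text{dataset}}^{-1})$. `curve_at_level()` applies this
per MCMC draw for every active level below the requested one; at the master
level all components are integrated out this way.

### Observation models

Three record types, all expressed through dataset-specific annual survival.
Harvest acts as a pulse removing a fraction $h_d$ of each age class once per
annual cycle, so total annual survival is

$$\phi_{t,d} = (1 - h_d)\, S_d(t+1) / S_d(t),$$

with $h_d \sim \text{Uniform}(0, 2\tilde h_d)$ given a user-supplied rough
rate $\tilde h_d$ (an arbitrarily small value, e.g. 0.001, encodes an
unharvested population).

1. **Age-specific estimates.** $\text{logit}(\tilde\phi_{t,d}) \sim
   N(\text{logit}(\phi_{t,d}), \tau_{t,d}^{-1})$. The precision comes from
   the reported standard error via the delta method,
   $\tau = \tilde\phi^2(1-\tilde\phi)^2/\text{SE}^2$, or from fallbacks in
   fixed order: a confidence interval (SE = width/$2z$), a binomial sample
   size (SE $= \sqrt{\tilde\phi(1-\tilde\phi)/n}$), else a conservative
   default logit-scale SD of 1.0 (`default_logit_sd`).
2. **Age-range estimates** ("adult survival, ages 5+"): compared to the
   abundance-weighted mean $\sum_t \phi_{t,d} \pi_{t,d}$ over the range,
   where $\pi_{t,d}$ is proportional to the expected number alive at age
   $t$ — the cumulative product of annual survivals with the first age of
   the range as reference (an empty product, weight $\propto 1$).
3. **Catch-at-age cohorts**: counts $[C_1, \dots, C_T]$ are multinomial with
   cell probabilities given by the same cumulative-product age structure,
   assuming age- and time-constant harvest rates.

Two conventions here were genuinely open and are configurable:

* whether the abundance weights (and catch cell probabilities) use natural or
  total survival. Default: total (harvest-adjusted), since the standing age
  structure of a harvested population reflects total mortality
  (`range_weights_use_harvest = TRUE`);
* where open-ended ranges ("5+") close: `max_age = 60`, chosen so survival
  past it is negligible ($S(60) < 10^{-6}$) for any plausible large-mammal
  parameterisation.

## Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `tau_alpha`, `tau_beta` (per level) | 1, 0.1 | Gamma hyperprior on each precision; weakly informative, promotes shrinkage but is easily overwhelmed by data |
| `init_tau` (per level) | 0.1 | sampler initial value for each precision (the hyperprior governs it thereafter) |
| master priors | $\log a \sim N(\log 0.1, 1.5^2)$, $\log(b{-}1) \sim N(0, 1.5^2)$, $\log c \sim N(\log 0.01, 1.5^2)$ | weakly informative on the unconstrained scale, wide enough to cover mammalian-plausible bathtub shapes |
| `default_logit_sd` | 1.0 | conservative logit-scale SD for estimates with no precision information |
| `max_age` | 60 yr | closure age for open-ended ranges |
| `first_catch_age` | 1 | age of the first catch-count cell |
| MCMC settings | 3 chains × 15000 iterations, burn-in 5000, thin 10 | gives 3000 retained draws; convergence monitored by $\hat R < 1.1$ |

The `init_tau = 0.1` reading deserves a note: the precision settings could be
read either as initial values or as fixed constants; they are treated here as
initial values, with the Gamma hyperprior governing the precisions during
sampling, because fixing them would make the variance-component comparison
across the 16 model structures vacuous.

## Inference

The posterior is sampled by an adaptive random-walk Metropolis-within-Gibbs
sampler written for this model (the joint density is evaluated in compiled
code): componentwise Gaussian proposals whose step sizes adapt in batches of
50 toward a 0.44 acceptance rate during burn-in, plus a full-vector adaptive
Metropolis move (Haario-style, scale $2.38^2/d$, with a 5% fixed-scale
mixture component) whose covariance keeps adapting through the run. The
joint move matters: the master parameters and the taxonomic effects are
strongly correlated a posteriori — a common shift in the $\epsilon$'s can
partly impersonate a change in $a$ or $c$ — and componentwise updates alone
traverse that ridge very slowly. Sampling happens on the unconstrained scale
($\log a$, $\log(b-1)$, $\log c$, $\log \tau_k$, logit-scaled $h_d$), with
Jacobians included, so parameter-domain constraints can never be violated;
out-of-support proposals simply return $-\infty$.

Reproducibility is contractual: identical seed, settings and data give
bit-identical draws.

Convergence is assessed by the Gelman-Rubin potential scale reduction factor
$\hat R = \sqrt{\hat V / W}$ with $\hat V = \frac{n-1}{n} W +
(1 + \frac1m)\frac{B}{n}$ (the test suite cross-checks against
`coda::gelman.diag`, which adds a small degrees-of-freedom correction).
Model comparison uses DIC $= \bar D + p_D$ with Spiegelhalter's
$p_D = \bar D - D(\bar\theta)$ by default ($\bar\theta$ the posterior mean
of the unconstrained parameters); the variance-based $p_D = \text{var}(D)/2$
used by JAGS-family software is always computed alongside
(`pd_method = "variance"`), since $p_D$ is convention-dependent and only the
DIC *ranking* should be compared across software. DIC's known difficulty
counting parameters in missing-data models is the reason `dic()` reports
$p_D$ explicitly rather than hiding it.

## Prediction for data-free populations

`predict_prior_population()` builds the model-implied survival prior for a
new dataset of a fitted species — e.g. an unharvested population
($\tilde h = 0.001$) of a species whose other populations were studied. Two
equivalent routes:

* **simulate** (default): per retained draw, add
  $\epsilon \sim N(0, \tau_k^{-1})$ for each active level below species.
  Fast, no refit.
* **refit**: append a dataset whose survival data are entirely missing and
  rerun the MCMC; its effect is then sampled as a parameter with no
  likelihood term.

The two agree to first order; they are not identical, because in the refit
the appended effect also contributes (one shrinkage observation) to the
dataset-level precision posterior. The predictive intervals are, by
construction, at least as wide as the species-level intervals at every age —
this monotone widening is asserted in the tests.

## The synthetic-data generator

`generate_collection()` inverts the full generative model: group effects
drawn per level, multipliers assembled, true harvest-adjusted survival
computed, and the three record types emitted — logit-normal noise (default
logit SD 0.2, i.e. $\tau = 25$, comparable to a survival estimate with
SE ≈ 0.03–0.05) for the survival estimates, and multinomial catch vectors
with Poisson totals (mean 200, a typical harvest-record size). The written
standard-error column encodes the noise precision exactly under the
delta-method rule, so reading a simulated file back reconstructs the
generating $\tau$.

The default study shape — 2 subfamilies, 4 species, 6 studies, 8 datasets,
level SDs 0.2, ages 0–9 each present with probability 0.75, one range
estimate per dataset, catch cohorts only for the harvested half — is a
deliberately scaled-down version of a real multi-species seal meta-analysis,
sized so that the full simulation studies (20-replicate parameter recovery
at the default MCMC settings; 20-replicate DIC model-selection recovery at
shortened chains) run in minutes. `phocid_fixture()` freezes one such
collection (seed 42) used across the test suite.

What the generator does *not* emulate — and hence what passing recovery
tests cannot certify about real data: estimates whose errors correlate
across ages within a study (the model assumes independent observation
noise); apparent-survival bias from permanent emigration in mark–recapture
sources; age- or time-varying harvest rates and reporting rates in catch
records; and taxonomies where the true variation is not well described by
discrete nested levels.

## Numerical choices and degenerate inputs

* Survival estimates of exactly 0 or 1 are truncated to
  $[10^{-6}, 1 - 10^{-6}]$ with a warning (the logit must be finite);
  rejecting them would discard otherwise usable records.
* $\tilde h_d$ must lie in (0, 0.5] so that $\text{Uniform}(0, 2\tilde h_d)$
  is a valid rate prior; larger values are a load-time error with guidance.
* Initialisation: master parameters at their prior medians, effects at 0,
  precisions at `init_tau`, all jittered per chain; non-finite starting
  densities trigger bounded re-initialisation.
* Ties in `model_select()` are broken by the deterministic spec order
  (subset size, then lexical).
* A dataset with no survival records contributes only its prior terms — the
  mechanism behind the refit prediction route — and this additivity is
  tested exactly.

## Known limitations

Proportional hazards constrain every dataset to the same hazard *shape*;
species with genuinely different senescence patterns (e.g. populations with
no documented senescent increase) can be mis-shaped by pooling, and for
data-rich populations a restricted, single-population analysis may be
preferable. Harvest rates are age- and time-invariant. Reported survival is
taken as true survival (no permanent-emigration correction). DIC is the
only model-comparison criterion offered. The sampler is a random-walk
scheme: adequate for the ~25–100 parameter models here, but chain lengths
should be increased (and $\hat R$ watched) for much larger taxonomies.
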