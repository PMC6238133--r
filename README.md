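# natmort

Hierarchical Bayesian estimation of U-shaped age-specific natural mortality
for long-lived mammals, from the kind of sparse, heterogeneous data the
literature actually offers: age-specific annual survival estimates (with SE,
CI, sample size, or nothing), survival estimates over age ranges ("subadult
survival, ages 1–4", "adult survival, 5+"), and catch-at-age counts from
harvest records. It was designed for multi-species meta-analyses of
hard-to-study marine mammals such as polar phocid seals, where no single
population has enough data, but applies to any taxon with a bathtub-shaped
hazard.

## The model in brief

A reduced additive Weibull (RAW) baseline hazard

    S(t) = exp{ −(at)^b − (at)^(1/b) − ct },
    λ(t) = ab(at)^(b−1) + (a/b)(at)^(1/b−1) + c,     a > 0, b > 1, c ≥ 0

gives high juvenile mortality, a low adult plateau near `c`, and a senescent
rise. Datasets differ by proportional hazards, `λ_{t,d} = ψ_d λ_t` (so
`S_d = S^{ψ_d}`), with log multipliers decomposed over a nested taxonomy:

    log ψ_d = Σ_{k ∈ K_d} ε_k,   ε_k ~ N(0, 1/τ_k),   τ_k ~ Gamma(α_k, β_k),

where `K_d` is any subset of {subfamily, species, study, dataset} — 16
candidate variance-component structures, compared by DIC. Observations enter
on the logit scale with delta-method precisions; harvest acts as a pulse,
`φ_{t,d} = (1 − h_d) S_d(t+1)/S_d(t)`, with `h_d ~ Uniform(0, 2h̃_d)` given a
rough harvest rate `h̃_d`. Inference is by an adaptive
Metropolis-within-Gibbs sampler with a full-vector adaptive joint move;
convergence by Gelman-Rubin R̂. See the methods vignette
(`vignettes/hierarchical-mortality.Rmd`) for the full account.

## Worked example

Simulate a small multi-species collection from a known truth, fit the
species + dataset model, and inspect the master hazard parameters:

```r
library(natmort)

sim <- generate_collection(raw_params(a = 0.054, b = 2.6, c = 0.006),
                           taxonomy = simulate_taxonomy(2, 4, 6, 8),
                           level_sd = c(species = 0.2, dataset = 0.2),
                           seed = 42)
sim$data
#> Mortality data collection: 8 datasets, 6 studies, 4 species, 2 subfamilies
#>   67 age-specific estimates, 8 age-range estimates, 4 catch cohorts

model <- build_model(sim$data, model_spec(c("species", "dataset")))
fit <- run_mcmc(model, n_chains = 3, n_iter = 15000, burn_in = 5000,
                thin = 10, seed = 1)
subset(fit$summaries, parameter %in% c("a", "b", "c"))
#> # A tibble: 3 × 7
#>   parameter   mean      sd     q2.5 median  q97.5  rhat
#>   <chr>      <dbl>   <dbl>    <dbl>  <dbl>  <dbl> <dbl>
#> 1 a         0.0582 0.00379 0.0499   0.0585 0.0651  1.00
#> 2 b         2.98   0.429   2.45     2.88   4.17    1.02
#> 3 c         0.0194 0.0183  0.000703 0.0143 0.0708  1.01
```

The 95% credible intervals cover the generating values (a = 0.054, b = 2.6,
c = 0.006), and all R̂ are below 1.1 (here the maximum over all 25
parameters is 1.019). Survival curves at any level of the hierarchy, with
the lognormal bias correction for levels above the deepest fitted one:

```r
curve_at_level(fit, model, "species", "sp01", ages = c(1, 10))
#> # A tibble: 2 × 9
#>   level   key     age S_mean   S_lo  S_hi hazard_mean hazard_lo hazard_hi
#>   <chr>   <chr> <dbl>  <dbl>  <dbl> <dbl>       <dbl>     <dbl>     <dbl>
#> 1 species sp01      1  0.516 0.392  0.625       0.248     0.178     0.338
#> 2 species sp01     10  0.136 0.0616 0.228       0.180     0.126     0.247
```

In this simulated collection `sp01` happens to be a high-mortality species
(its hazard multiplier drew above 1): about 52% of its animals survive the
first year and 14% reach age 10. A survival *prior* for a population of
`sp01` with no data at all (e.g. unharvested, rough rate 0.001) — wider
than the species interval because it adds dataset-level variation:

```r
predict_prior_population(fit, model, "sp01", h_rough = 0.001, ages = 10,
                         seed = 2)
#> # A tibble: 1 × 9
#>   level      key     age S_mean   S_lo  S_hi hazard_mean hazard_lo hazard_hi
#>   <chr>      <chr> <dbl>  <dbl>  <dbl> <dbl>       <dbl>     <dbl>     <dbl>
#> 1 prediction sp01     10  0.152 0.0255 0.366       0.182    0.0856     0.325
```

`model_select(data)` fits all 16 variance-component structures and returns
the DIC-ranked table; `read_mortality_data()` / `write_mortality_data()`
handle the documented CSV schema; `read_dryad_layout()` loads a locally
downloaded data deposit in that schema. A thin command-line front end is
installed as `exec/natmort` (subcommands `simulate`, `fit`, `model-select`,
`predict-prior`, `summarize`, `show-config`), writing a reproducibility
manifest beside every artifact.

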