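# morphdyn

Tools for asking whether a colour-pattern polymorphism is governed by
negative frequency-dependent selection (NFDS), and whether its
year-to-year dynamics are repeatable rather than drift. The package
estimates the NFDS parameter `D` — the slope of the per-generation
frequency change `Δp` on the current frequency `p` near the internal
equilibrium — hierarchically across replicate localities from
morph-count time series, classifies the implied dynamics, tests whether
fluctuations dampen through time, and compares observed fluctuation
magnitude against an NFDS + genetic drift null. It also fits relative
fitness functions to frequency-manipulation transplant experiments
(linear versus sigmoidal, compared by WAIC), estimates the
striped-versus-melanic recapture advantage from blocked release
experiments, and tests structural-variant genotype data for an excess
of heterozygotes.

All estimation is data-frame-first and tidyverse-native: model inputs
are tibbles, fitted objects have `tidy()`/`glance()` methods and
`autoplot()` displays, and a bundled synthetic-data generator
(`sim_morph_series()`) emulates a replicated multi-decade field survey
so the whole pipeline can be exercised, calibrated, and stress-tested
without field data. Bayesian models run in JAGS through rjags; every
sampler takes an integer seed and identical inputs give identical
output.

## Worked example

Simulate four localities followed for 20 years under NFDS of known
strength, estimate `D` hierarchically, and compare the fluctuations
against drift:

```r
library(morphdyn)

cfg <- sim_config(n_localities = 4, years_per_locality = 20,
                  D_true = c(-0.6, -0.5, -0.45, -0.35),
                  p_eq_true = c(0.3, 0.5, 0.65, 0.8), seed = 2)
sim <- sim_morph_series(cfg)
head(sim$counts, 4)
#> # A tibble: 4 × 6
#>   locality  year host       n_striped n_green n_melanic
#>   <chr>    <dbl> <chr>          <int>   <dbl>     <int>
#> 1 L01       2000 Adenostoma         4      14         0
#> 2 L01       2000 Ceanothus         14      36         2
#> 3 L01       2001 Adenostoma         6      16         2
#> 4 L01       2001 Ceanothus         11      32         3

fit <- fit_d_model(sim$counts,
                   mcmc = mcmc_settings(chains = 4, warmup = 4000,
                                        iter = 4000),
                   seed = 3)
fit
#> <nfds_d_fit> 4 localities; mean posterior-median D = -0.84
#> # A tibble: 4 × 6
#>   locality      D  D_lo   D_hi p_eq_hat class
#>   <chr>     <dbl> <dbl>  <dbl>    <dbl> <chr>
#> 1 L01      -0.830 -1.47 -0.292    0.329 converging
#> 2 L02      -0.837 -1.61 -0.260    0.495 converging
#> 3 L03      -0.663 -1.27 -0.137    0.663 converging
#> 4 L04      -1.03  -1.89 -0.348    0.754 dampened_oscillation
```

All slopes are negative — frequencies are pulled back toward a
locality-specific equilibrium — and the fitted equilibria track the
observed mean frequencies almost perfectly:

```r
equilibrium_vs_mean(fit, sim$counts)
#> # A tibble: 1 × 3
#>       r  p_value n_localities
#>   <dbl>    <dbl>        <int>
#> 1 1.000 0.000138            4
```

Point estimates of `D` are systematically more negative than the
generating values (here, truths of -0.6 to -0.35): mean-reversion
estimates from short series carry a finite-sample bias toward stronger
reversion. The intervals remain wide enough to cover the truth; see the
limitations section of the methods vignette
(`vignette("nfds-methods")`) before interpreting `D` point estimates
from series of a couple of decades.

Is the observed fluctuation magnitude more than NFDS + drift at
`Ne = 110` would produce?

```r
drift_null_analysis(fit, Ne = 110, reps = 100, seed = 4)
#> <drift_null> Ne = 110 ; 100 reps/locality; Fisher chi2 = 11.37 df = 8
#> # A tibble: 4 × 6
#>   locality observed null_mean p_value fold_excess  reps
#>   <chr>       <dbl>     <dbl>   <dbl>       <dbl> <int>
#> 1 L01        0.0360    0.0337   0.386       1.07    100
#> 2 L02        0.0431    0.0348   0.149       1.24    100
#> 3 L03        0.0399    0.0314   0.109       1.27    100
#> 4 L04        0.0321    0.0333   0.545       0.966   100
```

No excess here — as expected, since these data were generated with
modest exogenous forcing. `ne_sensitivity()` repeats the comparison
over a grid of `Ne` values.

A one-sided Monte-Carlo test for heterozygote excess at a structural
variant (57 observed heterozygotes among 602 individuals against a
Hardy-Weinberg expectation of 8.15%):

```r
het_excess_test(57, 602, 0.0815, reps = 1000, seed = 5)
#> # A tibble: 1 × 7
#>   observed     n expected_het_freq expected_count  p_mc p_exact  reps
#>      <dbl> <dbl>             <dbl>          <dbl> <dbl>   <dbl> <dbl>
#> 1       57   602            0.0815           49.1 0.134   0.135  1000
```

Other entry points: `test_dampening()` (are fluctuations shrinking
through time?), `fit_fitness_function()` / `fit_experiment_d()` /
`fit_morph_advantage()` (transplant experiments),
`assign_clusters()` + `het_excess_from_genotypes()` (genotype
clustering and heterozygote excess), `theory_curves()` +
`plot_theory_curves()` (closed-form `Δp` curves for the classical
processes), and `run_pipeline()` (simulate-or-read, estimate, classify,
test, and write provenance-stamped outputs in one call).

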