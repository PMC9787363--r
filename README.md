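# songmark

Integrated Bayesian estimation of animal population sizes from
mark–recapture surveys and passive acoustic monitoring.

## The problem

Mark–recapture gives unbiased population-size estimates only when
detection is modelled well, and it struggles when an environmental
covariate affects both abundance and catchability. Passive acoustic
recorders detect animals through a completely different mechanism, so
combining the two data streams in one likelihood can break that
confounding and sharpen the estimates. `songmark` implements a joint
model for multi-guild communities (species, families or feeding guilds
sharing parameters) surveyed over repeated site visits, for field
ecologists who run mist-netting or trapping protocols alongside
automated recorders.

## The model

For guild *i* at sampling event *z* (one visit to one site), the latent
population size is

    N_iz ~ Poisson(D_iz),        log D_iz = Σ_q ν_iq X_zq

Captures follow a homogeneous Poisson process in continuous time with
rate `r_iz` per hour (`log r_iz = Σ_q ρ_iq W_zq`) over a capture period
of `T` hours, so

* the time to first capture of each individual is `Exponential(r_iz)`,
  and an individual is caught at all with probability `1 − exp(−r_iz T)`;
* the number of distinct individuals caught is
  `n_iz ~ Binomial(N_iz, 1 − exp(−r_iz T))`;
* a caught individual first seen at time `c` accrues
  `y ~ Poisson(r_iz (T − c))` recaptures.

The acoustic survey scores `L` listening periods of `M` hours each;
vocalizations reach the recorder as a Poisson process with per-capita
rate `λ_iz` per hour (`log λ_iz = Σ_q ψ_iq G_zq`), giving

    a_iz ~ Binomial(L, 1 − exp(−λ_iz N_iz M))

The two observation processes are conditionally independent given
`N_iz`, which is marginalized out of the joint likelihood by finite
summation, so the posterior over the regression coefficients is sampled
with an adaptive Metropolis-within-Gibbs sampler and `N` is
re-materialized afterwards by the law of total probability. A
mark–recapture-only model (the same likelihood without the acoustic
factor, which collapses to `n_iz ~ Poisson(D_iz (1 − exp(−r_iz T)))` by
Poisson thinning) is built in for comparison. Convergence is assessed
with split-chain Gelman–Rubin R-hat; intervals are 95%
highest-posterior-density intervals.

## Worked example

Simulate the default three-guild scenario (20 sites visited twice,
`T = 6` h of netting, `L = 20` two-minute listening periods per event)
and fit the integrated model:

```r
library(songmark)

sim <- sm_simulate(seed = 42)
sim$data
#> <sm_data> 3 guilds x 40 events; 1028 first captures, 1028 histories; 23 acoustic detections (L = 20)

fit <- sm_fit(sim$data, chains = 3, iter = 10000, burnin = 2000, seed = 1)
tidy(fit)
#> # A tibble: 12 × 6
#>    term   estimate std.error conf.low conf.high  rhat
#>    <chr>     <dbl>     <dbl>    <dbl>     <dbl> <dbl>
#>  1 nu_A0   5.33      0.302    4.71      5.89     1.03
#>  2 nu_B0   3.03      0.359    2.31      3.72     1.02
#>  3 nu_C0   5.93      0.600    4.80      7.12     1.00
#>  4 nu_1    0.00431   0.00428 -0.00428   0.0121   1.04
#>  5 nu_2    0.163     0.0579   0.0456    0.271    1.01
#>  6 rho_A0 -4.30      0.309   -4.88     -3.68     1.03
#>  7 rho_B0 -3.52      0.374   -4.24     -2.76     1.02
#>  8 rho_C0 -6.16      0.603   -7.34     -5.00     1.00
#>  9 rho_1  -0.00484   0.00439 -0.0134    0.00343  1.04
#> 10 psi_A0 -6.92      0.420   -7.69     -6.06     1.01
#> 11 psi_B0 -4.69      0.478   -5.66     -3.79     1.00
#> 12 psi_C0 -7.25      0.686   -8.64     -5.97     1.01
```

`nu_*0` are log expected abundances per event (guild A:
`exp(5.33) ≈ 206` birds in range of the nets), `rho_*0` log captures
per bird-hour (guild A: `exp(-4.30) ≈ 0.014`, i.e. a ~8% chance of
catching a given bird in 6 h), `psi_*0` log per-capita acoustic
detection rates per hour, and `nu_1`, `nu_2`, `rho_1` the covariate
effects (the generating values here were 0.01, 0.15 and −0.01). Every
`rhat` is below 1.1, so the three chains agree. The latent population
sizes come back per cell:

```r
posterior_abundance(fit, n_draws = 200) |> head(3)
#> # A tibble: 3 × 9
#>   guild event  site visit     n  mean    sd conf.low conf.high
#>   <chr> <int> <int> <int> <int> <dbl> <dbl>    <int>     <int>
#> 1 A         1     1     1    16  315.  84.7      190       506
#> 2 A         2     1     2    21  375. 106.       211       598
#> 3 A         3     2     1    14  317.  88.6      143       479
```

so at site 1, visit 1, 16 distinct birds of guild A were caught and the
model estimates roughly 190–510 were present. `autoplot(fit)` draws the
interval plot; `run_simulation_study()` and `compare_precision()` script
the integrated-versus-mark-recapture comparison; `effort_tradeoff_sweep()`
explores how listening effort trades off against netting effort.

A thin command line ships in `inst/cli/`:

```sh
inst/cli/songmark simulate --seed 1 --out data/
inst/cli/songmark fit data/ --model integrated --seed 1 --out fit/
```

Every run writes a JSON manifest with the seed, configuration and
convergence summary.

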