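# kinmix

Close-kin mark-recapture (CKMR) estimates animal abundance and vital rates
from the kin pairs — parent–offspring pairs (POPs) and half-sibling pairs
(HSPs) — discovered among genotyped animals: offspring "mark" their parents,
and the rarity of kin matches among samples reflects how many adults there
are. The method assumes that, conditional on age and sex, every animal is
equally catchable. When samples come from hunters or fishers, sampling effort
varies in space, and if relatives stay near each other (limited dispersal)
kin pairs are over-represented and a naive, nonspatial estimator is biased
low.

`kinmix` is a simulation laboratory for quantifying that bias in a
long-lived mammal population. It provides:

- **Life history**: reduced additive Weibull survival
  `S_a = exp(-(η₁a)^η₂ - (η₁a)^(1/η₂) - η₃a)` and logistic fecundity
  `f_{a,g} = 1/(1+exp(-ν_{g,1}(a-ν_{g,2})))`, with Leslie-matrix calibration
  of η₃ so the growth rate λ = 1 (`calibrate_stationarity()`).
- **Individual-based simulator** (`simulate_study()`): 10,000 animals on a
  10×10 grid over 60 years with full pedigree tracking; mortality, movement
  and within-cell breeding in sequence under a postbreeding census; four
  dispersal regimes (complete mixing, Gaussian-kernel all ages,
  juvenile-only, none) crossed with four spatial sampling regimes (uniform,
  2:1 gradient, 10:1 gradient, north-edge only); lethal sampling of 100
  newly dead animals per year in years 41–60.
- **Kinship tallies** (`find_pops()`, `find_hsps()`,
  `tally_comparisons()`): sufficient statistics `n` (comparisons) and `m`
  (matches) per covariate cell.
- **Naive CKMR estimator** (`fit_ckmr()`): penalized Poisson
  pseudolikelihood over POP and HSP cells,

  ```
  Λ(θ) = Σ_cells { nP(θ) − m log nP(θ) }
         + ½ Σ_i ((η̃_i − η_i)/σ_i)² + ½ Σ_{g,i} ((ν̃_{g,i} − ν_{g,i})/τ_{g,i})²
  ```

  minimized over θ = (R₀, η̃₁..₃, ν̃₁,₁..ν̃₂,₂) with `nlminb`, Hessian-based
  standard errors, and derived ages-2+ abundance, survival and fecundity
  curves (broom-style `tidy()`/`glance()` methods included).
- **Mixing diagnostics** (`mixing_diagnostics()`): kin-pair versus all-pair
  sampling-distance distributions and two-sample Kolmogorov–Smirnov tests.
- **Scenario runners** (`run_bias_study()`, `run_ks_power_study()`):
  replicate studies of proportional abundance bias and KS power, with
  `ggplot2` figures (`plot_bias_study()`, `plot_ks_power()`,
  `plot_distance_histogram()`, `autoplot()`).

## A worked example

Simulate the assumptions-met scenario (complete mixing, uniform sampling),
fit the naive model, and measure abundance bias:

```r
library(kinmix)
lh  <- calibrated_life_history()
sim <- simulate_study(kin_config(lh = lh, seed = 42))
tal <- tally_comparisons(sim$samples, pedigree = sim$pedigree)
tal
#> <kin_tallies>
#>   samples: 2000
#>   POP cells: 19372 (comparisons 3873000, matches 221)
#>   HSP cells: 1260 (comparisons 3834184, matches 647)

fit <- fit_ckmr(tal, ckmr_priors(lh))
proportional_bias(true_abundance(sim)$abundance,
                  derived_abundance(fit)$abundance)
#> [1] 0.01449
```

Among the 2,000 sampled carcasses the pedigree contains 221 true
parent–offspring pairs and 647 cross-cohort half-sibling pairs; the fitted
ages-2+ abundance overshoots the simulation truth by 1.4% on this replicate
(replicate-averaged bias is under 1%). Under dispersal limitation with
spatially restricted sampling the same pipeline produces severe negative
bias — the point of the exercise:

```r
res <- run_bias_study(dispersal_modes = c("complete_mixing", "none"),
                      sampling_modes = c("uniform", "restricted_north"),
                      reps = 30, seed = 1, lh = lh)
summarise_bias_study(res)
plot_bias_study(res)
```

Diagnosing the problem from the data alone:

```r
mixing_diagnostics(simulate_study(kin_config(lh = lh, dispersal = "none",
                                             n_per_year = 25, seed = 7)))
#> # A tibble: 2 × 5
#>   kind  n_kin n_null statistic  p_value
#>   <chr> <int>  <int>     <dbl>    <dbl>
#> 1 POP      15 110900     0.987 3.97e-13
#> 2 HSP      47 110900     0.987 0
```

Kin pairs sit at distance zero while the null distribution spans the grid:
the KS test flags incomplete mixing even at 25 samples per year.

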