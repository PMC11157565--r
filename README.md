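# swarmselect

Two-stage multi-objective feature selection for high-dimensional
small-sample (HDSS) regression — the regime of metabolomics tables where
a few dozen samples carry hundreds to tens of thousands of ion-intensity
features, most irrelevant and many mutually redundant, and the outcome
is a continuous indicator.

**Stage 1 (filter + wrapper).** Features are ranked by
minimum-redundancy maximum-relevance mutual information — the first
feature maximizes *I(f, Y)*, each next one maximizes
*I(f, Y) − (1/|S|) Σ<sub>s∈S</sub> I(f, s)* — then sequential forward
search walks ranked prefixes, scores each by 10-fold cross-validated PLS
regression, and keeps the prefix with minimum RMSE as the candidate set.

**Stage 2 (Pareto swarm).** A multi-objective particle swarm searches
subsets of the candidate set, minimizing jointly the subset size
*f₁ = |S|* and the cross-validated error
*f₂ = √(1/n Σ (y − ŷ)²)*. Particles live in [0, 1]^D with threshold
decoding; velocities follow
*v′ = w v + c₁r₁(p<sub>best</sub> − x) + c₂r₂(p<sub>leader</sub> − x)*
with a nonlinearly decreasing inertia weight
*w(t) = (w<sub>max</sub> − w<sub>min</sub>)(t/T − 1)² + w<sub>min</sub>*
and linearly scheduled acceleration factors (c₁: 2.75 → 1.25,
c₂: 0.5 → 2.25). Leaders come from a bounded archive of non-dominated
solutions (crowding-distance truncation, adaptive-grid roulette). The
result is a Pareto front: for each affordable subset size, the best
subset found, with out-of-fold RMSE, R² and MAE per member.

The package is tidyverse-native: data frames in, tibbles out,
`tidy()`/`glance()` on every fitted object, `autoplot()` for the
RMSE-vs-size trace and the Pareto front.

## Worked example

```r
library(swarmselect)

# 60 samples x 200 features: 4 relevant, 3 noisy copies, 193 irrelevant
sim <- synth_hdss(n_samples = 60, n_relevant = 4, n_redundant = 3,
                  n_noise = 193, noise_sd = 0.5, seed = 7)

fit <- mcmopso(sim$data, y, iterations = 60, pop_size = 30, seed = 7)
fit
#> Two-stage swarm feature selection (mrmr + cmopso)
#>   features: 200  -> candidate: 18  -> front of 5 subset(s)
#> # A tibble: 5 × 4
#>   n_features  rmse    r2   mae
#>        <int> <dbl> <dbl> <dbl>
#> 1          1 1.55  0.227 1.31
#> 2          2 1.33  0.450 1.09
#> 3          3 1.07  0.662 0.886
#> 4          4 0.545 0.908 0.449
#> 5          5 0.539 0.910 0.435
```

Stage 1 cut 200 features to an 18-feature candidate set (CV RMSE 0.974);
the swarm then traded size against error: one feature explains 23% of
the variance, four reach R² = 0.91 at RMSE 0.545 — close to the
generating noise floor of 0.5 — and the fifth buys almost nothing. The
minimum-RMSE member recovers three of the four planted relevant features
plus the copy that substitutes for the fourth:

```r
dplyr::slice_min(tidy(fit), rmse)$features[[1]]
#> [1] "rel_4"    "noise_52" "rel_1"    "red_3"    "rel_2"

autoplot(fit)            # Pareto front in objective space
autoplot(fit$candidate)  # forward-search RMSE trace
```

A command-line interface wrapping the same functions ships in
`inst/scripts/swarmselect.R` (`run`, `rank` and `synth` subcommands);
`write_results()` serializes any fit as CSVs plus a JSON manifest that
reproduces the run byte-for-byte given its seed.

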