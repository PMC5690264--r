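# bymweights

Bayesian small-area disease mapping with explicit control over the two
pieces of spatial structure the analysis rests on: **adjacency** (which
areas are neighbours, extracted from a polygon map) and **spatial
weights** (how strongly each pair of neighbours is coupled).

The package was built for small-area ecological studies of health
outcomes -- the motivating setting is fall-injury hospitalisation among
seniors across a few hundred census dissemination areas -- where counts
are sparse, some areas have almost no population-at-risk, and conclusions
about risk surfaces and risk factors can hinge on how the spatial prior is
specified. Intended users are spatial epidemiologists and biostatisticians
who would otherwise script this workflow around WinBUGS and a desktop GIS.

## The model

For area `i` with observed count `Y_i` and indirectly standardized
expected count `E_i`:

    Y_i ~ Poisson(lambda_i)
    log lambda_i = log E_i + alpha + x_i' beta + S_i + U_i

with unstructured effects `U_i ~ N(0, nu_u)` and spatial effects `S`
following the intrinsic conditional autoregressive (ICAR) prior for
symmetric weights `w_ij`:

    S_i | s_-i ~ N( sum_j w_ij s_j / w_i+ ,  nu_s / w_i+ )

Priors: flat `alpha`, `beta_q ~ N(0, 10^4)`, and `Gamma(0.5, 0.0005)` on
both precisions (a prior that centres the random-effect sd near 0.05 with
~1% mass below 0.01 or above 2.5; `Gamma(0.001, 0.001)` is the built-in
sensitivity alternative). Fitting is by a compiled Metropolis-within-Gibbs
sampler (2 chains, 20,000 burn-in + 10,000 retained each by default) with
sum-to-zero recentring of `S` each sweep.

Weight schemes: `equal_weights()` (`w_ij = 1`) and `product_weights()`
(`w_ij = v_i v_j` for per-area `v` = population, density, or expected
count). `compare_weight_schemes()` fits every scheme on an identical data
path and compares fits by DIC with a decision margin (default 5).

The other half of the package audits adjacency:
`extract_queen_adjacency()` matches polygon vertices exactly or within a
tolerance, `compare_adjacency()` quantifies what a deficient digital map
(same boundary vertex stored with close-but-different coordinates) does to
the neighbourhood structure, and the synthetic generator
(`synthetic_scenario()` / `simulate_scenario()`) manufactures maps with
exactly that defect plus stratified populations, covariates and counts
with known ground truth.

## Worked example

Simulate a 10x10-area study in which senior population is patchy (high-
and low-population areas interleaved), the spatial field was generated
under expected-count weights, and 10% of shared map vertices carry
discrepant coordinates; then audit the adjacency and compare weight
schemes:

```r
library(bymweights)

sc <- synthetic_scenario(n_rows = 10, n_cols = 10, jitter_fraction = 0.1,
                         weight_scheme_true = "expected",
                         population_pattern = "patchy",
                         population_range = c(2, 80),
                         population_gradient = 0.97, nu_s_true = 0.8,
                         seed = 42)
d <- simulate_scenario(sc)

# exact vertex matching on the flawed map misses true neighbour pairs
compare_adjacency(d$map$true_adjacency,
                  extract_queen_adjacency(d$map$map, tolerance = 0))
#> adjacency audit: 684 true vs 658 generated neighbor entries
#>   undercount error: 0.0380 (3.8%)
#>   pairs missed: 13, pairs invented: 0

tot <- area_totals(d$table)
E   <- unname(expected_counts(d$table))
cmp <- compare_weight_schemes(
  tot$Y, E, NULL, d$map$true_adjacency,
  schemes = c("equal", "expected"),
  sampler = sampler_config(burn_in = 5000, keep = 5000, seed = 42))
cmp$dic_table
#>     scheme   Dbar     pD    DIC converged
#> 1    equal 476.26 70.602 546.86      TRUE
#> 2 expected 472.40 65.750 538.15      TRUE
cmp$winner
#> [1] "expected"
sapply(cmp$summaries, function(s) s$exceedance$counts)
#>        equal expected
#> P>0.50    37       39
#> P>0.75    26       28
#> P>0.90    24       23
#> P>0.95    20       20
```

Reading the output: the flawed map loses 13 of 342 true neighbour pairs
(3.8% of directed entries) under exact matching -- a tolerance at least
the recorded jitter magnitude recovers all of them. Expected-count
weights fit these data better than equal weights by 8.7 DIC (beyond the
margin of 5, so the scheme is flagged the winner), and slightly more
areas clear the `P(r_i > 1) > 0.5` exceedance threshold under them. The
hyperprior facts quoted above are computed by
`implied_sd_prior(0.5, 0.0005)`: median sd 0.047, tail probability 1.17%.

The full pipeline -- extraction, standardization, univariate covariate
screening, percentile-dummy recoding, per-scheme fits, sensitivity rerun,
artifact files -- is `run_full_analysis(analysis_config(...))`; a thin
command-line front end with `simulate` / `adjacency` / `standardize` /
`fit` / `compare` / `run` subcommands lives at `inst/cli/bymweights.R`.

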