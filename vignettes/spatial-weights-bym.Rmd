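---
title: "Spatial structure in Bayesian small-area disease mapping: adjacency, weights, and the BYM model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spatial structure in Bayesian small-area disease mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Small-area ecological studies of health outcomes -- the motivating case is
hospitalisation for fall injuries among seniors across a few hundred census
dissemination areas -- estimate an area-level relative risk surface and the
effects of area-level covariates from sparse counts. Risks are stabilised by
borrowing strength across space through a conditional autoregressive prior,
and the analyst must specify the *spatial structure* doing the borrowing in
two parts:

1. **adjacency** -- which areas are neighbours. Queen contiguity (any shared
   boundary point or vertex) is the standard choice, but the extracted
   adjacency is only as good as the digital map: the same physical boundary
   vertex can be recorded with close-but-different coordinates in the two
   polygons that share it, so an exact-coordinate match silently drops true
   neighbour pairs;
2. **weights** -- how strongly each neighbouring pair is coupled. The
   conventional choice is equal (binary) weights. The alternative examined
   here weights each pair by the product of an area-level variable --
   senior population, its density, or the expected case count `E_i E_j` --
   so that information is borrowed preferentially between areas with
   similar, well-populated risk profiles, and only minimally from
   near-empty neighbours.

`bymweights` implements the whole workflow: synthetic data with known truth,
adjacency extraction and auditing, weight construction, model fitting,
and comparison of weight schemes by the deviance information criterion.

## The model

For area $i = 1, \dots, n$ with observed count $Y_i$ and expected count
$E_i$ from indirect standardization,

$$Y_i \sim \text{Poisson}(\lambda_i), \qquad
\log \lambda_i = \log E_i + \alpha + x_i'\beta + S_i + U_i .$$

The convolution random effect has an unstructured component
$U_i \sim N(0, \nu_u)$ and a spatially structured component $S$ with the
intrinsic conditional autoregressive (ICAR) law for symmetric positive
weights $w_{ij}$:

$$S_i \mid s_{-i} \sim N\!\left(\frac{\sum_j w_{ij} s_j}{w_{i+}},
\frac{\nu_s}{w_{i+}}\right), \qquad w_{i+} = \sum_j w_{ij},$$

equivalently the improper joint density
$\propto \exp\{-\tfrac{1}{2\nu_s}\sum_{i<j} w_{ij}(s_i - s_j)^2\}$. The
spatial dependence parameter of the proper CAR family is fixed at its
maximum of one, which is what normalising the weights inside the
conditional accomplishes. Expected counts come from internal indirect
standardization over the 10 age-sex strata (2 sexes x ages 65-69, 70-74,
75-79, 80-84, 85+): $z_k = \sum_i Y_{ik} / \sum_i N_{ik}$ and
$E_i = \sum_k N_{ik} z_k$, which forces $\sum_i E_i = \sum_i Y_i$. The
relative risk is $r_i = \lambda_i / E_i$; its posterior exceedance
probability $P(r_i > 1 \mid Y)$ flags elevated-risk areas.

### Priors

* $\alpha$: improper flat;
* $\beta_q \sim N(0, 10{,}000)$ (sd 100) independently;
* $1/\nu_u,\ 1/\nu_s \sim \text{Gamma}(0.5,\ 0.0005)$ (shape, rate). This
  centres the implied random-effect *standard deviation* near 0.05 with
  about 1% total prior probability of sd below 0.01 or above 2.5 --
  `implied_sd_prior(0.5, 5e-4)` computes these facts through the Gamma
  distribution function. The alternative $\text{Gamma}(0.001, 0.001)$ is
  wired in as the default sensitivity hyperprior.

### Weight schemes

`equal_weights()` sets $w_{ij} = 1$. `product_weights()` sets
$w_{ij} = \max(v_i v_j, \text{floor})$ for a nonnegative per-area variable
$v$ -- population, population density, or expected count -- with the floor
(default $10^{-6}\times$ the median positive product) keeping $w_{i+} > 0$
when an area's value is zero. All schemes are the same operation with a
different $v$; $v \equiv 1$ recovers equal weights exactly. The stored form
is always unnormalised (the form a `car.normal`-style sampler consumes);
`normalized_rows()` is a reporting view whose rows sum to one.

Two scale facts matter. Rescaling $v$ by any $c > 0$ multiplies all weights
by $c^2$ and changes nothing after $\nu_s$ adapts -- the row-normalised
weights are invariant. But the *floor* is not scale-free: a floored pair
can be arbitrarily weakly coupled relative to the rest of the graph. The
comparison pipeline therefore normalises each value vector to mean one and
floors the values themselves at 0.01 before forming products, so
near-empty areas stay weakly-but-finitely coupled; leaving them effectively
detached makes their spatial effects unidentified and destabilises the
deviance. The synthetic generator applies the same normalisation so that
its `nu_s_true` genuinely governs the scale of the simulated field.

## Fitting

`run_mcmc()` is a Metropolis-within-Gibbs sampler (compiled, seeded from
R's RNG so chains are bit-reproducible). Per sweep:

1. each $S_i$ by scalar random-walk Metropolis against Poisson likelihood
   times the ICAR pairwise-difference prior, then recentring of $S$ to sum
   to zero with the shift absorbed into $\alpha$ -- the standard
   identifiability fix for the improper ICAR, valid under the flat
   intercept prior;
2. each $U_i$, then $\alpha$ and each $\beta_q$, by scalar random-walk
   Metropolis;
3. conjugate Gibbs draws
   $1/\nu_u \sim \text{Gamma}(a + n/2,\ b + \sum_i U_i^2/2)$ and
   $1/\nu_s \sim \text{Gamma}(a + (n-1)/2,\ b + \tfrac12 \sum_{i<j}
   w_{ij}(S_i - S_j)^2)$; the rank correction $n-1$ assumes one connected
   component, and disconnected maps or island areas are rejected at model
   construction.

Step sizes adapt toward an acceptance rate of 0.44 (the scalar-update
optimum) during burn-in only, so detailed balance holds for the retained
draws. Defaults follow the reference protocol: 2 chains, 20,000 burn-in
iterations, 10,000 further iterations retained per chain (20,000 posterior
samples), thin 1 -- the run lengths fix the totals but not the thinning,
and thin 1 is assumed. Zero expected counts are floored at `e_floor`
(default $10^{-4}$) with a warning naming the areas.

## Diagnostics and comparison

`diagnostics_report()` computes per-parameter Gelman-Rubin statistics
(the classical $\sqrt{(W(m-1)/m + B/m)/W}$, clipped below at 1),
batch-means Monte Carlo error ratios (30 batches), the DIC decomposition,
and the spatial fraction. Conventions:

* **DIC** uses the full Poisson deviance including the $\log Y_i!$ terms,
  with the plug-in deviance evaluated at the posterior means of the
  $\lambda_i$ ("stochastic parents" convention), so
  $p_D = \bar D - \hat D$ and $\text{DIC} = \bar D + p_D$; one code path
  evaluates both terms, making DICs comparable across weight schemes on
  the same data. A scheme is declared the better fit only when its DIC
  undercuts the runner-up by more than a margin, default 5.
* **Spatial fraction**: per iteration,
  $\text{sd}(S) / (\text{sd}(S) + \text{sd}(U))$ with empirical area-level
  standard deviations. Whether the sd- or variance-based form is intended
  varies across the disease-mapping literature; both are computed and the
  sd-based form is canonical here (recorded in the report itself).
* **Exceedance counts** use strict inequality at each probability
  threshold: an area with $P(r_i > 1) = 0.50$ exactly is not counted at
  the 0.50 threshold.
* **Convergence gate** for reported comparisons: $\hat R \le 1.1$ and MC
  error below 5% of the posterior sd, evaluated on the intercept and
  regression coefficients -- the parameters whose tables are reported.
  The variance hyperparameters' diagnostics are computed and returned,
  but their characteristically slow mixing under scalar updates does not
  by itself veto a comparison.

The pipeline (`run_full_analysis()`) screens covariates univariately under
equal weights at the 95% credible level (screening is done under equal
weights regardless of which scheme later wins), then fits the final model
under every requested scheme with a shared data path and seed, and reruns
the comparison under the sensitivity hyperprior. Covariates whose
categorisation is judgement-laden can be re-expressed as percentile
category dummies: `percentile_dummies()` emits three quartile indicators
(Q2, Q3, Q4 against a Q1 reference) at nearest-rank percentiles 25/50/75,
with ties at a cutpoint falling to the lower category. Three dummies with
a bottom reference is the self-consistent reading of a final model with
exactly three indicator terms, even where such workflows are loosely
described as "quintiled"; the choice is recorded in the run metadata.

## The synthetic generator

`synthetic_scenario()` + `simulate_scenario()` emulate the data a regional
health unit would hold, with known truth:

* an `n_rows x n_cols` lattice whose vertices are displaced by a clamped
  Normal offset (consistently across incident polygons, so areas are
  irregular but truth adjacency is intact), with a configurable fraction
  of shared vertices stored as independently perturbed per-polygon copies
  -- the digitisation failure mode that makes exact-match queen extraction
  undercount true adjacency. The generator records the largest distance
  between duplicate copies; any matching tolerance at least that large
  recovers the truth exactly;
* a stratified senior population over the 10 age-sex strata, uniform
  within area-specific subranges. Default stratum rates rise roughly
  five-fold from the 65-69 to the 85+ group, reflecting the age gradient
  of fall injuries. The spatial pattern is a smooth urban-rural gradient
  by default, or interleaved high/low patches; a configurable fraction of
  areas is forced to near-zero population-at-risk, reproducing the
  near-empty areas that make weight specification consequential;
* spatially structured standardized covariates built from area centroids
  plus noise;
* random effects $S$ drawn exactly from the constrained ICAR law (via the
  eigendecomposition of the weighted graph Laplacian; the constrained
  covariance is $\nu_s$ times its pseudo-inverse) under the scenario's
  true weight scheme, $U$ iid Normal, and stratum-level counts
  $Y_{ik} \sim \text{Poisson}(N_{ik} z_k r_i)$ whose area totals follow
  the model's $\text{Poisson}(E_i r_i)$.

One master seed drives derived per-stage streams (map, population,
covariates, ICAR, unstructured, counts), all recorded in the output;
identical scenario and seed give bit-identical datasets.

What the generator does **not** emulate: real DA geometry (areas are
perturbed quadrilaterals, so vertex counts and shapes are simpler than
digitised boundaries), multi-polygon areas, covariate measurement error,
and any individual-level fall process. Passing tests therefore demonstrate
correctness of the algorithms and calibration under the model's own
assumptions, not robustness to the ways real census data violate them.
The magnitude of real vertex discrepancies is unknown; the jitter sd is a
free scenario parameter (default $10^{-3}$ map units against unit-sized
cells).

## Operating conditions used by the checks

The package's stochastic self-checks run at deliberately modest problem
sizes:

* *coefficient calibration*: 20 replicates of the default scenario (10x10
  lattice, $\alpha = 0$, $\beta = (0.3, 0.02)$, $\nu_s = 0.3$,
  $\nu_u = 0.05$, equal-weights truth) at the default sampler; the 95%
  intervals should cover the truth in at least 80% of replicates;
* *model selection*: 10 replicates generated under expected-count weights
  with interleaved high/low population patches (`population_pattern =
  "patchy"`, range 2-80, gradient 0.97) and $\nu_s = 0.8$, fitted with
  2 x (5,000 + 5,000) chains. Patchiness puts high and low
  population-at-risk areas next to each other -- the regime in which
  product weights genuinely differ from equal weights; under a smooth
  population surface the two schemes are locally indistinguishable (a
  product weight is then a rescaled equal weight) and no criterion can
  separate them. The spatial variance was set by a pilot power analysis
  so that the comparison has adequate power at $n = 100$; at these
  settings the expected-count fit beats equal weights by more than the
  DIC margin in the large majority of replicates.

## Known limitations

* The ICAR variance parameters mix slowly under scalar updates; runs
  aimed at precise posterior summaries of $\nu_s$ should lengthen the
  chains or thin less aggressively than the location-parameter defaults
  require.
* Only one connected component is supported; per-component constraints
  for fragmented maps are deliberately out of scope.
* The proper CAR with estimated dependence parameter, reparameterised
  convolution models, and stochastic (e.g. Bernoulli) weight models are
  out of scope; the package compares deterministic weight
  specifications.
* Shapefile input is not supported (no shapefile reader among the
  package's dependencies); maps are exchanged as GeoJSON.
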