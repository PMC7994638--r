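---
title: "Behavioral-state movement models and resource selection with stateRSF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Behavioral-state movement models and resource selection with stateRSF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(stateRSF)
```

## What the package models

stateRSF implements a two-part analysis of large-mammal GPS telemetry,
developed around wild pig (*Sus scrofa*) movement in the southeastern
United States:

1. **Behavioral-state segmentation.** Hourly movement paths are summarized
   as step lengths $\ell_t$ and turning angles $\varphi_t$ and modeled with
   a hidden Markov model (HMM). Conditional on the latent state
   $S_t \in \{1,\dots,K\}$, step lengths follow a gamma distribution
   parameterized by mean $\mu_k$ and standard deviation $\sigma_k$
   (shape $(\mu_k/\sigma_k)^2$, rate $\mu_k/\sigma_k^2$), and turning
   angles follow a wrapped Cauchy with angular mean $\mu_{\varphi,k}$ and
   concentration $\rho_k \in [0,1)$. With states ordered by ascending step
   mean, the three states of the default models read as *resting* (short
   steps, turns concentrated near $\pi$), *foraging* (short-to-intermediate
   steps, reversals), and *traveling* (long, directionally persistent
   steps).
2. **Resource selection.** Decoded states feed used-available logistic
   resource selection functions (RSFs) at two orders of selection:
   second-order (where home ranges sit in the study area; plain logistic
   GLM per sex-season) and third-order (which locations are used within
   the home range, per behavioral state; logistic GLMM with a per-animal
   random intercept). Coefficients on standardized covariates are
   back-transformed to odds ratios per natural increment (100 m for
   distance covariates, 10 percentage points for canopy cover).

## Track preprocessing

`parse_fixes()` reads fix tables (ISO-8601 UTC timestamps, projected
meters); `clean_track()` collapses duplicate timestamps, removes fixes at
or after mortality, and drops the first 48 h after collar deployment to
avoid anesthesia-biased movement. The 48-h rule is half-open: a fix at
exactly deployment + 48 h is kept. `regularize()` thins 30-min schedules
to the 1-h target (every other fix) and splits tracks into bursts wherever
the inter-fix gap departs from 3600 s by more than a 300-s tolerance.
Gaps are never interpolated — fabricated fixes would enter the likelihood
as data — so irregular stretches simply start new bursts, and fragments
shorter than 3 fixes (too short to contain a turning angle) are dropped
and counted. Seasons follow forage availability: January-April is the
low-forage season, May-December high-forage.

Turning angles are signed (counterclockwise positive) and wrapped to
$(-\pi, \pi]$ with the exact-reversal boundary mapped to $+\pi$. The hour
covariate is the clock hour of the step's starting fix, kept continuous in
$[0, 24)$.

## The HMM likelihood and its fitting

Transition probabilities vary with time of day through a multinomial logit
with the diagonal as reference,

$$\eta_{ij}(h) = \beta^0_{ij} + \beta^c_{ij}\cos\tfrac{2\pi h}{24}
  + \beta^s_{ij}\sin\tfrac{2\pi h}{24}, \qquad
  \Gamma_{ij}(h) = \frac{e^{\eta_{ij}(h)}}{1 + \sum_{j'\neq i} e^{\eta_{ij'}(h)}}.$$

The hour effect is a first-order cosinor because clock time is circular;
a linear-in-hour form (`tod = "linear"`) and a time-homogeneous form
(`tod = "none"`) are available where the diel structure is absent or not
of interest. The initial distribution $\delta$ is estimated (applied at
every burst start) rather than fixed at the stationary distribution.

`forward_loglik()` computes the scaled forward recursion in compiled code;
the first step of each burst contributes only its step-length term since
its turning angle is undefined. `fit_hmm()` maximizes the likelihood by
BFGS with forward-difference gradients on a working scale: log means and
SDs, logit concentrations, unconstrained transition coefficients, and a
multinomial logit for $\delta$. Angular means are optimized as
unconstrained reals and wrapped to $(-\pi, \pi]$; the likelihood is
periodic in them, which keeps the objective smooth even when the optimum
sits at the $\pm\pi$ reversal boundary (a bounded transform would push
such optima toward infinite working values). Because the likelihood is
multimodal, fitting restarts from 25 random starting values by default:
gamma means log-uniform within a factor of 3 of quantile anchors of the
observed steps (25th/50th/90th percentiles for three states), SDs 0.5-1.5
times the drawn mean, concentrations uniform on (0.05, 0.9), angular means
drawn from $\{0, \pi\}$, transition intercepts uniform on $(-2, -1)$ with
zero cosinor terms. Convergence requires the optimizer's relative
function-change tolerance ($10^{-8}$, at most 500 iterations);
non-convergent starts are discarded and reported, and the best converged
start is returned with states relabeled by ascending $\mu_k$.

Like all gamma-mixture likelihoods, the HMM's likelihood is unbounded:
a state can spike on a single observation ($\sigma_k \to 0$, or
$\rho_k \to 1$ for turns), with arbitrarily large likelihood and no
descriptive value. Starts whose optimum degenerates this way
($\sigma_k < 10^{-4}$ times the median step, or $\rho_k > 0.999$) are
rejected along with non-convergent ones and flagged in the per-start
diagnostics.

Exact zero step lengths are rejected by default — collar jitter makes true
zeros rare, and a zero breaks the gamma density — with an optional
per-state zero-mass mixture (`zero_mass = TRUE`) for data where the
recorder truncates small displacements. State counts are compared by AIC
($-2\log L + 2k$ with $k = 4K$ emission parameters, $+K$ zero masses if
enabled, $3K(K-1)$ transition coefficients, $K-1$ initial-distribution
parameters), ties broken toward fewer states. `viterbi()` decodes the
most probable state path per burst, ties toward the lower state index.

## Home ranges, sampling and covariates

The study area is the minimum convex polygon of all locations buffered by
1.2 km (Minkowski dilation with rounded corners). Home ranges are 95%
isopleths of a fixed-kernel utilization density with the bivariate
reference bandwidth $h = \sqrt{(s_x^2 + s_y^2)/2}\, n^{-1/6}$ — one scalar
bandwidth on both axes, matching classical home-range practice — evaluated
on a 30-m grid padded three bandwidths beyond the data and renormalized.
The isopleth is the smallest set of cells reaching 95% of the mass (cells
ranked by density), so the enclosed mass always lies in [0.95, 0.96] on
these grids. Availability and within-home-range use are sampled on a 90-m
systematic lattice (every third 30-m pixel) anchored at the raster origin
rather than at a random phase, which makes samples pixel-aligned and
reproducible.

Habitat covariates are Euclidean distances to each vegetation class
(exact distance transform between cell centers; a location in a class has
distance 0 to it), point-to-segment distances to stream and road
polylines, and percent canopy cover. Covariates are screened pairwise at
Pearson $|r| > 0.6$, dropping the lower-priority member, and standardized
($z = (x - \bar{x})/s$) on the combined used + available fitting set.
Rasters are exchanged as ESRI ASCII grids — a plain-text interchange
format readable by standard GIS software — and vectors as GeoJSON.
Projected metric coordinates are required; geographic input declared as
`crs = "longlat"` is converted by a local equirectangular projection,
which is adequate at study-area extents of tens of kilometers.

## RSF models and reporting

Used-available logistic regression estimates the RSF up to its intercept
(the intercept absorbs the used:available sampling ratio), so reports
present only covariate effects. Second-order models are plain GLMs per
sex-season; third-order models are GLMMs with a per-animal random
intercept, fitted by adaptive Gauss-Hermite quadrature (9 nodes by
default; 1 node is the Laplace approximation). The package also exposes
its own adaptive quadrature implementation of the marginal likelihood
(`glmm_marginal_loglik()`), used in the test suite to cross-check the
fitted models against direct numerical integration. Odds ratios per
increment use Wald 95% intervals transformed with the coefficient; a
covariate is called significant when the interval excludes 1. Decoded
states enter third-order designs as fixed labels — state uncertainty is
not propagated — and no multiple-testing correction is applied across the
twelve third-order models. Model fit is summarized by the rank-based
(concordance) AUC, ties counted one half.

The full grid over two sexes, two seasons and two candidate state counts
is 8 HMM fits, 4 second-order GLM reports and 12 third-order GLMM reports
(3 states per stratum); `run_pipeline()` executes it end-to-end and all
of its stages derive from one top-level seed, making reruns
byte-identical.

## The synthetic study system

Because collar data of this kind are not openly archived, the package
generates a study system with the statistical structure the analysis
assumes:

* **Landscape** (`make_landscape()`): a categorical raster from a smoothed
  Gaussian random field thresholded at the mixing-weight quantiles —
  contiguous patches with exact class proportions, default 50% upland
  pine, 25% bottomland hardwood, 10% shrub/herb, 8% upland hardwood, 4%
  developed, 3% other, emulating a pine-dominated industrial forest —
  plus meandering stream/road polylines and a smooth canopy field elevated
  under forested classes.
* **Telemetry** (`simulate_track()`, `simulate_study()`): tracks drawn
  from the HMM with default emission parameters per sex and season (step
  means from ~10 m resting to ~420 m traveling males; reversal-centered
  turns at rest, forward-concentrated turns while traveling). Published
  state summaries for this system do not include the angular
  concentrations, so the generator fixes $\rho = (0.40, 0.30, 0.75)$ for
  resting/foraging/traveling: moderate concentration for the two
  encamped states, strong directional persistence while traveling, in
  line with movement-HMM fits for ungulates. Transition intercepts give
  a diagonally dominant matrix (0.8 stay / 0.1 switch); optional cosinor
  terms add nocturnal travel and diurnal rest.
* **Selection** (`simulate_rsf_points()`): used points by rejection
  sampling with acceptance $\propto \exp(\beta^\top x(s) + b_a)$,
  $b_a \sim N(0, \tau^2)$. With a fixed number of used points per animal
  the intercept cancels from the accepted spatial pattern, so
  random-intercept recovery is tested on directly simulated Bernoulli
  responses instead, and the point-process route checks coefficient
  recovery end-to-end.

Movement is simulated ballistically (landscape-free) and selection
point-wise rather than as one habitat-biased random walk: coupling them
would conflate the two estimands, which the analysis itself treats
separately. Consequences worth keeping in mind: simulated tracks are not
range-resident, so synthetic "home ranges" are larger and looser than
those of a territorial animal; selection strength in the synthetic system
is set by the user, not emergent; and passing tests demonstrate the
estimators recover known structure, not that any particular field system
satisfies the model.

## Numerical choices and problem sizes

Quadrature tolerances of $10^{-6}$ (marginal likelihoods, density
normalization) and oracle tolerances of $10^{-10}$ (forward likelihood vs
exhaustive path enumeration) are used in the tests. The test suite and
the acceptance script size their simulations to run on a single CPU:
parameter-recovery refits use 30 tracks of 1,000 hourly steps (30,000
steps, 25 starts), the end-to-end pipeline fixture uses 3 animals per sex
per season with 400-step tracks on a 15 x 15 km landscape, and coverage
checks use 200 replicates of 400-point designs. The analysis scripts
under `analysis/` run the same workflow at the same fixture scale.

## Known limitations

* Covariates other than hour, hierarchical/random-effect HMMs,
  forward-backward state probabilities and pseudo-residual diagnostics are
  out of scope; decoding is hard (Viterbi) only.
* Only gamma/wrapped-Cauchy emissions are implemented.
* Home-range estimation is classical fixed-kernel with href; no LoCoH,
  Brownian-bridge or autocorrelated-KDE estimators.
* The equirectangular fallback projection is not a substitute for a
  proper projected CRS over large extents.
* Availability sampling is clipped to the mapped raster extent; a study
  area buffered beyond the landscape loses the overhanging lattice points
  (reported by a warning).
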