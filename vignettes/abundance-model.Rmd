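---
title: "Joint modeling of tracks, counts and detection in dual-platform aerial surveys"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Joint modeling of tracks, counts and detection in dual-platform aerial surveys}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(polarabund)
```

## The estimation problem

Springtime aerial surveys for polar bears on sea ice yield sparse and
heterogeneous data. Two aircraft with different sensors fly transects over
a large grid; one detects groups by automated thermal imagery verified on
photographs (plus extra visual sightings with no distance information),
the other relies on human observers and photo review with perpendicular
distances. Both record bear *tracks*, again under different protocols:
systematic photo sampling on one side, observer counts of distinct tracks
on the other. No single stream supports abundance estimation on its own —
counts are in the dozens over hundreds of thousands of km² — so this
package fits them all in one joint likelihood, and the synthetic-data
module generates every stream from known parameters so that the whole
pipeline can be exercised and calibrated without access to (non-public)
survey data.

## Model structure and assumptions

**Closed population with daily redistribution.** A fixed number `N` of
bear groups is present throughout the survey; each day they reallocate
across grid cells with probabilities
`pi_{s,t} = A_s exp(nu_{s,t}) / sum_s' A_s' exp(nu_{s',t})`, where `A_s`
is the saltwater area of the cell. Closure stabilizes estimation when
degrees of freedom are scarce; the cost is that the estimate must be read
as the average number of groups present while the survey ran. The daily
redistribution in the simulator is an independent multinomial draw each
day — no movement kernel, no day-to-day autocorrelation.

**Habitat smooths.** `nu` carries penalized cubic regression spline
smooths (`mgcv` bases, maximum basis dimension 6, sum-to-zero constraint
absorbed) of ice concentration, RSF, and standardized easting and
northing, with no intercept (the softmax is invariant to one). Smoothing
parameters get `Gamma(shape 0.05, rate 0.005)` hyperpriors (mean 10). Two
fixed effects join the smooths: the open-water indicator (`ice < 1%`) with
its coefficient pinned at −50, which forces `pi` to effectively zero in
ice-free cells while keeping the objective smooth, and the latent track
intensity as a linear term.

**Track submodel.** Track counts are approximated as a "blocky" spatial
Poisson process with cell-day intensity `Z_{s,t} = exp(x' beta)`, where
`x` holds an intercept, linear+quadratic standardized distance to land,
linear+quadratic ice concentration, and linear RSF (deliberately simple
polynomial regression — no smooths). The photo stream sees
`Binomial(P, 1 - exp(-B Z))` with `B = 0.012` km² per examined photograph;
the observer stream sees `Poisson(L eta Z)`. The scaling `eta` absorbs
both the unknown effective strip width for tracks and how observers
delineate "a track", and is identified only jointly with the photo data
(the test suite demonstrates the likelihood is exactly flat along
`intercept + log eta` when photo rows are removed). Tracks are spatially
smeared, continuous features, so the Poisson independence assumption is
knowingly misspecified; the package keeps the clean binomial/Poisson forms
and surfaces lack of fit through randomized quantile residuals rather than
modeling overdispersion.

**Detection.** Counts are thinned by `p = theta * a`. Coverage `a` is
`L * 1.2 / A` for the visual platform (0.6 km strip either side, motivated
by the observed distance distribution) and photo footprint over `A` for
the thermal platform, clipped to 1. Thermal detectability comes from
binomial flyover trials; visual detectability is
`g(0) * mean of exp(-x^2 / 2 sigma^2) over [0, w]` with `w = 600` m.
`g(0)` cannot be estimated from single-platform distance data and is a
fixed scenario input — the interface requires it explicitly, and the
conventional scenarios are 0.6, 0.8 and 1.0. Lower `g(0)` mechanically
inflates abundance, which is why results are reported as a scenario
family. The distance likelihood conditions on detection, so `g(0)` enters
only through `p`, never through the distance density. A uniform–half-normal
mixture detection function (certain detection to a 350 m photo-reach
breakpoint, half-normal decline beyond) is available for comparison by
AIC; the join at the breakpoint is continuous — the weakest assumption
consistent with a uniform segment, since nothing in the problem pins down
a jump size.

**Group size and absolute abundance.** Sizes are shifted-Poisson
(`(g - 1) ~ Poisson(mu_g - 1)`), whose mean MLE is the sample mean; one
`mu_g` is shared across platforms (platform-specific means are
descriptively close, and the counts are too sparse to support two
parameters). `N* = mu_g N`, with a delta-method SE and 95% log-based
intervals `N* exp(±1.96 sqrt(log(1 + CV^2)))` — multiplicatively
symmetric, so `lower * upper = N*^2`.

## Marginalization and numerics

The joint negative log likelihood sums the track, count, flyover,
distance, and group-size terms with the Gaussian smoothing prior. Spline
coefficients are random effects integrated out by the Laplace
approximation; the TMB template in `src/` is evaluated with exact
derivatives, the inner Newton solve locates the coefficients' conditional
mode, and the outer quasi-Newton (`nlminb`) drives the marginal gradient
below ~1e-3 in typical fits (the convergence report records the achieved
norm and whether the marginal Hessian was positive definite; intervals are
suppressed when it is not).

Numerical choices that matter:

- **Smoothing parameters** are optimized on the log scale as penalized
  fixed parameters carrying their Gamma log-prior (empirical-Bayes
  handling, the standard practice for this model class), with full Laplace
  integration over `(alpha, log lambda)` available via
  `integrate_lambda = TRUE`. Profiling keeps the marginal Hessian
  well-behaved at these sample sizes.
- **Rank-deficient penalties.** Each centered smooth has a one-dimensional
  unpenalized (linear) null space; the Gaussian prior is normalized with
  the pseudo-determinant over the penalized subspace and the data supply
  curvature along the rest.
- **Log-scale likelihood evaluation.** Occupancy is computed as a
  log-softmax and Poisson terms take their mean on the log scale, so cells
  gated to `exp(-50)`-level probabilities can never underflow to an exact
  zero mean inside the inner optimization (`0 * log 0` is what breaks
  Laplace otherwise). Binomial photo-presence terms use a robust logit
  parameterization for the same reason.
- **Concurvity guard.** If the standardized distance-to-land and northing
  covariates correlate beyond 0.9, the distance-to-land smooth is dropped:
  near-duplicate smooths leave an exactly flat unpenalized direction and
  the Laplace log-determinant degenerates. In the synthetic geometry (a
  straight coastline along one lattice edge) the two are exactly
  proportional, so default synthetic fits use four smooths; real
  geographies with moderate correlation keep all five.
- **Track effect scale.** The track covariate enters the abundance
  predictor as `Z` standardized by its grand mean. Natural-intensity scale
  was chosen over log scale because the gate cells (`Z` near zero) would
  otherwise dominate the covariate range; with a reported track effect
  near zero the choice is not empirically distinguishable, and the
  standardization at least makes the coefficient scale-free.
- **Identifiability housekeeping.** Parameters whose data stream is empty
  (no distances, no trials, no track rows, ...) are frozen at their
  starting values rather than left to wander; starting values are crude
  moment estimates (uniform-occupancy abundance, distance-only `sigma`,
  photo-rate intercept), not the truth.
- **Coverage clipping.** `a` is clipped to 1; counts recorded where no
  effort exists are rejected at validation rather than silently dropped.

## What the generator emulates — and what it does not

`make_grid()` builds a planar equal-area lattice (default 20 × 20 cells of
25 km) with land along the southern edge, a coastal saltwater gradient,
and region flags (east/west halves plus two nested reporting
sub-rectangles). `make_covariates()` draws a smooth RSF field (sums of
radial Gaussian bumps), ice that declines in expectation through the
survey with the south melting first, and the derived open-water indicator;
optional missing ice values are refilled by inverse-distance weighting
(power 2, 8 neighbors) — a documented, deterministic stand-in for the
kriging applied to unreliable near-coast cells in real ice products.
`simulate_survey()` lays out parallel column transects (perpendicular to
the coast, cycling a seeded permutation so effort is space-filling), then
draws every data stream from the model's own distributions, including
counts with the exact `Poisson(xi N pi p)` means the estimator assumes.

Default scenario values are the study conditions: 400 cells, 10 days,
`N = 600` groups, `mu_g = 1.4`, `p_us = 0.67` with 12 flyover trials,
`sigma = 250` m, `w = 600` m, auxiliary scaling 1.67 (the observed ratio
of visual to thermal detections), and effort tuned to the published
platform totals — a photographic swath of 0.37 km (the ratio of photographed
area to track length flown) and about 1.4 examined photographs per km.
Typical realizations yield 50–60 detected groups, matching the scale of
the real survey. Values the record does not fix (track model coefficients,
habitat-preference coefficients, the photo-examination rate) were chosen
once to produce realistic track frequencies and a west-heavy, coast-heavy
density surface, and are exposed as scenario knobs.

The generator is deliberately a *faithful mirror* of the fitted model.
Passing recovery and coverage tests therefore demonstrates that the
estimator and its uncertainty quantification are internally correct at
realistic sparsity — not that the model is robust to the misspecifications
real data carry (track persistence and spatial continuity, movement
autocorrelation, preferential sampling, sensor-dependent detectability,
real coastlines and projections). Those are exactly the risks the
diagnostics module is for.

## Diagnostics

Randomized quantile residuals use the lower-CDF convention
`R = P(Y < y) + u P(Y = y)`, which is exactly Uniform(0,1) under a correct
model (the common shorthand `F(y) + u f(y)` exceeds 1 at the upper support
and is treated here as a typographical variant). Uniform deviates are
seeded and recorded so diagnostic runs reproduce. Uniformity is assessed
with a 10-equal-bin chi-squared test per submodel, reported for the four
encounter streams (photo tracks, observer tracks, thermal+auxiliary
counts, distance-platform counts).

## Problem sizes and runtime

The default study conditions (400 cells × 10 days, ~2 400 likelihood rows,
~20 spline coefficients, 18 outer parameters) fit in roughly 5–10 seconds
on one CPU. The test suite's calibration study runs 50 seeded replicates
of simulate-and-fit at those conditions; unit tests use a 10 × 10 grid
over 5 days. Monte-Carlo checks in the tests size their tolerance bands by
the replicate standard error (3 SE), not by fixed percentages.

## Known limitations

- `g(0)` is an assumption, not an estimate; results are a scenario family,
  and everything inherits that conditioning.
- The track submodel's independence assumption is wrong in a known
  direction (tracks are continuous features); its role is to supply a
  predictive index with propagated uncertainty, not a track census.
- Closure-with-redistribution ignores movement in and out of the study
  area during the survey window.
- The Laplace approximation is unchecked beyond the scalar-random-effect
  comparison against quadrature; very sparse counts with strongly
  non-Gaussian coefficient posteriors could degrade it.
- Abundance in never-surveyed habitat rests on the estimated
  covariate-density relationships; extrapolation risk grows with distance
  from sampled conditions.
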