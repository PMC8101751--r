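# polarabund

Joint spatio-temporal estimation of polar bear abundance from
dual-platform aerial surveys over sea ice.

## The problem

Polar bears occur at very low densities (on the order of 0.001–0.01
bears/km²) across enormous, remote areas of sea ice, which makes abundance
estimation from any single survey platform fragile. Springtime
instrument-based aerial surveys produce several weak but complementary data
streams: thermal-imagery detections verified on photographs, visual
detections by human observers, perpendicular distances to sighted groups,
photographic and observer records of bear *tracks* in snow, experimental
flyovers of known bears, and group-size observations — collected by two
aircraft with very different sensors and protocols. `polarabund` is for
quantitative ecologists who want to combine all of these streams in one
likelihood so that every component's uncertainty propagates into the final
abundance estimate.

## The model

A closed population of `N` bear groups redistributes itself daily over a
planar grid of cells indexed `s`, on survey days `t`:

- **Occupancy.** `π_{s,t} = A_s exp(ν_{s,t}) / Σ_s' A_s' exp(ν_{s',t})`,
  an area-weighted multinomial link with no intercept, where `A_s` is the
  saltwater area of cell `s`. The predictor `ν` carries penalized cubic
  regression spline smooths (basis dimension 6) of sea-ice concentration,
  a telemetry-derived resource selection function (RSF), and standardized
  easting/northing and distance to land; a fixed coefficient of −50 on the
  open-water indicator (`ice < 1%`) gates bears out of ice-free cells; and
  the latent track intensity enters as a linear fixed effect.
- **Tracks.** A "blocky" Poisson point process with cell-day intensity
  `Z_{s,t} = exp(x'_{s,t} β)` joins two data types: the number of examined
  photographs containing tracks is `Binomial(P_{s,t}, 1 − exp(−B Z_{s,t}))`
  with `B = 0.012` km² the photo footprint, and observer track counts are
  `Poisson(L_{s,t} η Z_{s,t})` with `η` a scaling that absorbs the unknown
  effective strip width for tracks.
- **Counts and detection.** Group counts in surveyed cell-days are
  `Poisson(ξ N π_{s,t} p_{s,t})` with compound detection
  `p = θ · a`: `a` is the fraction of the cell's saltwater habitat covered
  by effort (photo footprint for the thermal platform; a 1.2 km strip for
  the visual platform) and `θ` is per-group detectability — estimated from
  binomial flyover trials for the thermal platform, and
  `p_rus = g(0) ∫₀^w exp(−x²/2σ²) dx / w` from half-normal distance
  sampling (truncation `w = 600` m) for the visual platform. `g(0)`, the
  probability of detecting a group on the trackline, is never estimable
  from these data and is fixed per scenario (0.6, 0.8, 1.0).
- **Group size.** Observed sizes are shifted-Poisson,
  `(g − 1) ~ Poisson(μ_g − 1)`; absolute abundance is `N* = μ_g N`.
- **Inference.** All components enter one joint likelihood; spline
  coefficients get Gaussian smoothing priors with `Gamma(0.05, 0.005)`
  hyperpriors and are marginalized by the Laplace approximation (a TMB
  template authored in `src/`). Standard errors come from the marginal
  Hessian; intervals for abundance are 95% log-based
  (`N* · exp(±1.96 √log(1+CV²))`, multiplicatively symmetric).

Because real survey data of this kind are not public, the package includes
a first-class synthetic-data module (`make_grid()`, `make_covariates()`,
`simulate_survey()`) that draws every data stream from known parameters,
with defaults emulating the scale of a 2016-style Chukchi Sea survey
(400 cells of 25 km × 25 km, 10 survey days, 600 groups of mean size 1.4,
~50–60 detected groups).

## Worked example

```r
library(polarabund)

scenario   <- sim_scenario(seed = 7)           # default study conditions
grid       <- make_grid(20, 20, cell_km = 25, seed = 7)
covariates <- make_covariates(grid, T_days = 10, seed = 7)
survey     <- simulate_survey(grid, covariates, scenario)
survey
#> Dual-platform survey data
#>   track rows: 800 photo (us), 800 observer (ru)
#>   surveyed cell-days: 800 thermal, 800 auxiliary, 800 distance-sampled
#>   detections: 6 thermal, 7 auxiliary, 43 with distances
#>   group sizes recorded: 56; flyover trials: 9 of 12 detected

fit <- fit_abundance(survey, grid, covariates, g0 = 0.8)
fit
#> Joint spatio-temporal abundance model fit (Laplace-marginalized)
#>   g(0) scenario: 0.80 | converged: TRUE (|grad| = 1.47e-03)
#>   groups N-hat: 647.6 (SE 116.6)
#>   mean group size: 1.38 | total N*: 890 (95% CI 616-1287)
#>   detection: p_us 0.74, sigma 254 m, p_rus 0.42 (g0 0.8)
```

The generating truth here was `N = 600` groups of mean size 1.4, i.e.
`N* = 840` bears: the fit recovers the group abundance (647.6 vs 600),
the mean group size (1.38 vs 1.4), the half-normal scale (254 m vs 250 m)
and the thermal detection probability (0.74 vs 0.67), and the 95% interval
for `N*` comfortably covers the truth. Regional aggregation and
goodness-of-fit follow the same pattern as the headline fit:

```r
fit$region_table
#>   region  g0 estimate    se lower  upper
#> 1    all 0.8    890.4 168.8 616.0 1287.0
#> 2     us 0.8    185.5  69.4  91.3  377.0
#> 3     ru 0.8    704.9 141.0 478.1 1039.2
#> 4   pbsg 0.8    769.5 150.5 526.4 1124.9
#> 5 regehr 0.8     31.3  18.2  10.9   90.1

rqr_diagnostics(fit, seed = 1)
#> Randomized quantile residual diagnostics (10-bin chi-squared)
#>   submodel    n statistic p_value
#>  tracks_us  800      8.85  0.4512
#>  tracks_ru  800      2.23  0.9874
#>  counts_us 1600      4.99  0.8354
#>  counts_ru  800     16.68  0.0541
```

Lower assumed trackline detection always inflates abundance: refitting the
same data with `g0 = 0.6` and `g0 = 1.0` brackets the estimate above from
above and below. A survey on disk (the documented CSV schema written by
`write_survey_tables()`) can be fitted from the shell with
`Rscript scripts/fit_survey.R --dir tables/ --g0 0.8 --out results/`.

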