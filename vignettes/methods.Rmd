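---
title: "Methods: habitat-based density modelling of deep divers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: habitat-based density modelling of deep divers}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records how `divedsm` models deep-diver densities, which
choices were genuinely open, and what the synthetic validation does and
does not demonstrate. It states no empirical result beyond what the test
suite and `scripts/acceptance.R` themselves compute.

## The observation model

Each ~5 km effort segment contributes a count of individuals and an
effective area. For line transects the effective area is
`length × 2 × ESW`, with the effective strip width looked up per
(platform, Beaufort class, observation-height class); strip surveys use
a fixed 300 m half-width instead of a detection model. Counts are fitted
with a Tweedie GAM, log link, offset `log(effective area)`:

- **Tweedie family, 1 < p < 2.** Segment counts are zero-heavy and
  overdispersed; the compound Poisson–gamma branch of the Tweedie family
  puts positive mass at zero and scales variance as `phi * mu^p`. The
  power `p` is profiled on a fixed grid (1.10–1.90 by 0.05) using the
  series-evaluated log-likelihood; the dispersion is the Pearson
  estimate.
- **Smooths of basis dimension 4.** Each covariate enters as a cubic
  regression spline with `k = 4` and sum-to-zero constraint — three
  estimable curve degrees of freedom, deliberately austere given sparse
  sightings. Two variants are exposed: lightly penalised (REML-chosen
  smoothing inside the fixed basis; the default for final models and
  partial-effect plots) and unpenalised at exactly the basis dimension
  (`fixed_df = TRUE`). Whether the historical toolchain penalised inside
  the 4-df basis is not recoverable; we default the *enumeration* to the
  unpenalised variant because it is ~20× faster across hundreds of
  candidates and makes AIC differences a pure function of fit rather
  than of smoothing-parameter estimates, and keep the penalised variant
  for the models a user actually inspects.

## Multi-model inference

All 1–4-variable subsets of the candidate pool are fitted after
removing any pair with Pearson `|r| > 0.5` (strict inequality: a pair at
exactly 0.5 survives). Akaike weights are computed with a min-shift for
numerical stability and are invariant to adding a constant to all AICs;
variable importance is the summed weight of the models containing the
variable, ranked descending with alphabetical tie-break. The final model
takes the top four mutually uncorrelated variables by a greedy walk down
the ranking (a correlated variable is skipped in favour of the next
uncorrelated one). The ensemble is the smallest weight-descending prefix
of models whose cumulative raw weight reaches 0.8, the straddling model
included, and its map is the *weighted* mean of member maps with weights
renormalised inside the member set — plain averaging was also defensible
given the sources, but weighting follows the model-averaging literature
the workflow builds on. The single-model approximation is accepted when
the OLS `R^2` between the two maps (computed over all mutually valid
cells, equal to the squared Pearson correlation) is at least 0.9 — our
operationalisation of "close to 1", kept configurable.

Two decisions the sources leave open, fixed here: the Tweedie `p` is
profiled **once** (on the best single-variable model by AIC) and then
held fixed across all candidates, so that every AIC is computed under
the same family; and the candidate pool is a prior selection of 12
covariates by default (all four statics plus surface, subsurface and
deep-class dynamics) — exhaustively enumerating 1–4-variable subsets of
all 28 covariates yields 24,157 models, which is exactly why density
modellers pre-select variables before enumeration.

## Covariate derivation

- **Slope**: arctangent of the central-difference depth gradient over
  metric cell sizes, one-sided at borders. The east–west cell size uses
  `111.32 · cos(lat)` km per degree; a planar approximation would bias
  slopes northward across a 7° latitude span.
- **Roughness**: max − min depth over the 3×3 window, *centre
  included* — inclusion never changes max − min when the centre lies
  between its neighbours and matches the usual terrain-function
  convention; the wording "pixels surrounding the central pixel" is
  ambiguous, so the choice is recorded here.
- **Thermal-front gradient**: max − min over the *eight surrounding
  pixels, centre excluded*, following the front-detection operator's
  wording exactly; cells with fewer than three valid neighbours are set
  missing.
- **EKE** `= 0.5 (U² + V²)`, missing where either component is missing.
- **Climatologies**: per-cell mean and *population* standard deviation
  (divisor *n*) over the monthly layers — the study period is treated as
  the population, not a sample from it; cells missing in more than half
  the layers are masked. Gradients and EKE are computed **per monthly
  layer and then summarised** (the default), since the standard
  deviation of a gradient is meaningless if the gradient is taken of
  the climatological mean; the gradient-of-mean path is exposed for
  comparison and demonstrably differs whenever fronts move between
  months.
- **Resampling** to the common 0.083° grid aggregates by area-weighted
  means of contributing cells (spherical cell areas, so the
  area-weighted grid mean is conserved to numerical precision on
  aligned grids) and interpolates bilinearly when refining.
- **Shelf gaps**: the deeper depth classes are undefined where the
  seafloor is shallower than the class. Because predictions are wanted
  over the entire grid, those cells are filled from the nearest valid
  cell and flagged per cell in the raster's `filled` attribute; treat
  deep-class covariate values over the shelf as imputed, not observed.

## Survey processing

Polylines are cut into 5 km pieces; a residual shorter than 2.5 km is
merged into the last segment (tiny segments carry near-zero offsets and
destabilise the fit), a longer residual is kept. Segment lengths and
neighbour searches use haversine distances — adequate at this spatial
extent. Beaufort classes for the ESW lookup are `[0,1), [1,2), [2,3),
[3,4), [4,7]`; the Beaufort > 4 exclusion is applied before modelling
and the dropped effort is reported. Spatial autocorrelation of segment
counts is screened with Moran's I and Geary's C under row-standardised
k = 8 nearest-neighbour weights (the weight scheme is our choice; the
sources name only the test) with seeded permutation p-values. Note that
synthetic counts *are* spatially structured by construction — they are
driven by smooth spatial covariates — so on synthetic runs the
diagnostic correctly reports autocorrelation; it earns its keep on real
segment data.

## The synthetic world

The generator emulates, at the level needed to validate the pipeline: a
shelf widening northward, a slope band, an abyssal plain beyond 2000 m,
2–5 canyon channels incised across the slope following the shelf break;
monthly dynamic fields as depth-class baselines (cooler and quieter with
depth) plus a seasonal cycle and independent monthly Gaussian random
fields with squared-exponential covariance (default length scale 1°,
mimicking mesoscale structure; simulated by circulant embedding on a
doubled torus, exact up to clipped truncation eigenvalues); parallel
transects with platform/sea-state/height attributes drawn from an
effort mix matching published large multi-survey breakdowns (24/27/25/
16/8% across the five Beaufort classes); and ESWs of 0.3–1.6 km
decaying with sea state — order-of-magnitude plausible only, since the
surveys' detection conditions are not described in enough detail to
calibrate them.

Counts are exact compound Poisson–gamma draws with mean
`area × exp(intercept + Σ f_j(z_j))`, the smooths acting on z-scored
covariates (defaults: sigmoid in `mT_surface`, dome in `mEKE_200_600`,
amplitude 1, intercept `log(0.05)` per km², `p = 1.4`, `phi = 1.5`).
Draws are made integer by **stochastic rounding**
(`floor(y) + Bernoulli(frac(y))`): counts of individuals are integers,
and stochastic rounding preserves the mean exactly for any dispersion —
deterministic rounding would not (a low-dispersion draw concentrated at
0.12 rounds to zero always).

What the synthetic world does *not* emulate: ocean physics (fields are
statistically, not dynamically, plausible), species-specific group-size
distributions, responsive movement, seasonal habitat shifts, or
detection-function estimation (ESWs are inputs throughout). Passing
tests therefore demonstrate that the *inference machinery* recovers
known structure under realistic sampling noise — not that any particular
ecological conclusion transfers to real data.

Two honest consequences of the design, observed in validation runs:
profiling `p` on the rounded integer counts settles near the bottom of
the grid (~1.1) even for the correctly specified model, because integer
rounding genuinely makes the observed counts more discrete and
zero-massed than the latent continuous Tweedie — no analysis step
depends on recovering the latent `p`. And partial-effect fidelity
against the true smooth is assessed over the central 95% of the
covariate distribution: beyond the data the cubic spline extrapolates
linearly while a dome-shaped truth flattens, so the full-range
correlation is dominated by unsupported extrapolation (the same reason
partial-effect plots carry rug plots).

## Numerical choices and degenerate inputs

- Profile grid for `p`: 1.10–1.90 step 0.05; `p = 1` is accepted as an
  explicit Poisson limit (used by tests for its closed-form MLE).
- Offsets: refitting after scaling all effective areas by `c` shifts
  only the intercept (by `−log c`), leaving per-segment expected counts
  invariant and scaling unit-area densities by `1/c`; the suite asserts
  both faces of this identity at 1e-6 relative.
- Ties: AIC and importance ties break alphabetically; candidate subsets
  enumerate in (size, lexicographic) order — all orderings are
  deterministic.
- Zero-variance covariates are flagged and treated as correlated with
  nothing; candidates with too few distinct values to support the
  spline knots are screened out of the pool with a message. Canyon area
  is the typical casualty in synthetic runs: east–west transects that
  do cross the narrow canyon channels sample only a handful of grid
  rows, and the per-cell canyon area varies only with row, leaving a
  near-degenerate covariate.
- Constant count vectors make Moran/Geary undefined: flagged, not
  computed. Constant maps make the comparison `R^2` undefined: flagged.
- All generators are bit-reproducible from the scenario seed via
  deterministic per-stage sub-seeds; every stochastic analysis step
  (permutations, coefficient draws) takes an explicit seed.
- Problem sizes used by the validation suite: random-raster oracles up
  to 100×100; GAM recovery at n = 3000 segments and 10 candidate
  variables over 10 replicate seeds; pipeline tests on a 0.25°, 4-month
  scenario; the acceptance script runs the full 0.083°, 24-month
  default scenario. These sizes were chosen as the smallest that
  exercise each property cleanly.

## Known limitations

Densities are relative (no availability or perception bias correction);
the grid is treated as planar within cells (spherical areas, haversine
distances, but no projection); prediction-map uncertainty ignores
model-selection uncertainty (the single-model map's sd understates the
ensemble's spread); the vertical-averaging helper for level-based ocean
model output is provided for completeness but untested against any
specific ocean-model convention; and the R² comparison treats grid
cells as exchangeable observations, ignoring their spatial correlation.
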