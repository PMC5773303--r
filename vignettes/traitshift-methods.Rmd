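---
title: "Methods: spatially explicit body-size and phenology change analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spatially explicit body-size and phenology change analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

Museum collections of a widespread, explosively breeding frog span a century
and a continent. Two traits read off those vouchers — snout–vent length
(SVL, mm) and the Julian day of collection (a proxy for breeding date in a
species where most breeding happens within days) — carry strong latitudinal
and elevational clines. The analysis this package implements asks three
questions in sequence:

1. **Which climate variables explained the traits before rapid warming?**
   Decadal climate (mean temperature, precipitation, frost-free days, FFD)
   is attached to each pre-cutoff record (cutoff 1960 by default) and
   candidate mixed models are compared by AICc.
2. **Where did the traits change?** Thin-plate-spline surfaces of each trait
   on (latitude, longitude, elevation), bootstrapped 100 times per period,
   give per-pixel means and 95% intervals; pixels whose pre- and post-period
   intervals do not overlap are significant change, everything else is
   treated as zero change.
3. **Did climate change predict trait change?** Trait change at 484 random
   points is regressed on *proportional* climate change (change divided by
   the pre-cutoff level) with second-order polynomials, exponential spatial
   correlation, and per-point precision weights from the mapping step.

Every stage is driven through `run_pipeline()` or callable on its own, and a
synthetic-data module generates records and climate grids with known ground
truth so the whole chain is testable without any external downloads.

# The synthetic study system

`synth_params()` + `gen_climate_stack()` + `gen_specimens()` emulate the
statistical structure the downstream stages assume:

* **Climate fields.** Smooth fields on a 5-arc-minute grid: a dominant
  latitudinal gradient plus Gaussian-filtered noise. Temperature and FFD
  share a latent gradient field with the mixing weight calibrated by
  bisection so their cell-wise correlation lands within 0.03 of the target
  (default 0.87, the observed collinearity that motivates choosing FFD over
  temperature). Precipitation is weakly tied to the gradient.
* **Warming.** Decades ending after the cutoff are shifted by a smooth,
  spatially uneven field: temperature and FFD shift by `amplitude * u` with
  `u` in (0, 1) — warming everywhere, unevenly — and precipitation by
  `amplitude * v` with `v` in (−1, 1), so some areas become drier and some
  wetter. Defaults (+1.6 °C, +16 FFD, ±80 mm) give proportional FFD changes
  of roughly 0–14% and precipitation changes of roughly ±8%, the kind of
  spread against which quadratic change responses are identifiable.
* **Traits.** `log SVL = intercept_sex + beta_sex · (sFFD, sPrec,
  sFFD·sPrec) + u_year + e` and `Julian day = intercept + beta_phen ·
  (sFFD, sPrec) + u_year + e`, with scaled climate, a collection-year
  random intercept, and a residual with exponential spatial correlation
  `exp(-d/rho)` over horizontal distance. Trait coefficients default to the
  study-scale slopes (e.g. −42.4 days per SD of FFD for phenology; 0.112
  log-units per SD of precipitation for female size); variance components
  are back-solved from the benchmark marginal/conditional R² values so that
  the signal-to-noise of the synthetic system matches the motivating study system's
  (`sigma_year = c(size 0.032, phen 14)`, `sigma_resid = c(size 0.146,
  phen 28)`).
* **Breeding-season contamination.** A fraction of records is re-dated
  90–180 days after its breeding expectation, emulating non-breeding-season
  collections; the truth records which, so filter recall is measurable.
* **Composition.** Record counts default to the two study periods'
  body-size samples (679 pre, 585 post) and the observed sex ratio
  (38% female). Every year in a period receives at least one record.
  The phenology intercept is day 150: with the full per-SD slope acting on
  a compact domain the linear predictor spans roughly day 45–255, keeping
  essentially all probability mass inside the calendar and the record
  generation linear (a lower intercept would truncate early breeding dates
  at day 1 and visibly attenuate recovered slopes).
* **Domain.** The default grid is 48 x 48 cells of 5 arc-minutes (a 4° x 4°
  window) with an elliptical range mask and a synthetic DEM (smooth ridge
  plus relief). The spatial correlation range defaults to 1° — large enough
  that ignoring it would matter, small enough to be estimable on the domain.

What the generator does **not** emulate: real CRU anomaly construction,
temporally uneven collecting effort, observer or size-selective collection
bias, and real topography. Passing recovery tests therefore demonstrates
the estimators are correct under the assumed statistical structure, not that
the structure holds for any particular archive.

# Historic climate–trait models

`fit_lmm()` fits, by full maximum likelihood, the marginal model

    y ~ N(X beta, V),   V = sigma2_year Z Z' + sigma2_resid C(rho),
    C(rho)_ij = exp(-d_ij / rho)

with `Z` the year-indicator matrix and `d` the Euclidean distance between
record coordinates. The residual variance is profiled analytically, leaving
a 2-D optimization over `(log(sigma2_year/sigma2_resid), log rho)` solved by
Nelder–Mead from five deterministic starting points spanning the observed
distance scale; `beta` is the GLS solution given the variance parameters and
its covariance is `sigma2 (X' V0^-1 X)^-1`. A diagonal jitter of 1e-8 keeps
`C` positive definite at (near-)duplicate coordinates; there is no nugget
term beyond that.

Decisions worth knowing:

* **Coordinate space.** The default distance uses raw (lat °, lon °,
  elev m), matching what the field's standard correlation structures compute
  from supplied covariates; because metres dominate degrees in that metric,
  `scale_coords = TRUE` standardizes the axes, and any coordinate subset can
  be passed (the recovery simulations use horizontal coordinates, the space
  in which the generator defines its correlogram).
* **Candidate set and k.** Five models — intercept-only, FFD,
  precipitation, both, both plus interaction — with
  `k = p (fixed effects incl. intercept) + 3` variance/correlation
  parameters, constant across the set so delta-AICc is well defined.
* **Averaging.** Over the `delta AICc <= 2` set, full (zero-substitution)
  averaging with unconditional SEs
  `sum_i w_i sqrt(se_i^2 + (b_i - b_avg)^2)`; 95% CIs are Wald
  (±1.96 SE) and significance is "CI excludes zero". Conditional averaging
  is deliberately not offered as a default; zero substitution is the
  conservative convention.
* **R².** Marginal and conditional R² from the variance decomposition
  `varF / (varF + sigma2_year + sigma2_resid)` and
  `(varF + sigma2_year) / (...)` with `varF` the sample variance of the
  fixed-effect predictor.
* **Inference scale.** Plug-in Wald SEs understate the sampling spread when
  the correlation range is weakly identified: in our simulations at n = 350
  on the default domain the SE/SD ratio is about 0.89 (coverage 0.87), while
  at n = 680 — the larger of the two study-period sample sizes, at which the
  package's recovery simulations are run — the ratio is 1.06 and coverage is
  nominal. Users fitting small spatial samples should treat borderline
  significance with caution.

# Bootstrap trait maps and change detection

`fit_tps()` solves the order-2 thin-plate-spline system in three dimensions,

    [K + N lambda I, T; T', 0] [c; d] = [y; 0],   K_ij = -||x_i - x_j||,

with the affine basis `T = [1, x]` as null space (an affine trait surface is
reproduced exactly at any smoothing) and coordinates standardized to unit SD
internally so elevation cannot dominate. The reduction through the QR of `T`
and one eigendecomposition makes the whole GCV path cheap; `lambda = "auto"`
minimizes `V(lambda) = N RSS / (N - tr A)^2` over a log-spaced grid spanning
ten orders of magnitude around the kernel's spectral scale. Observation
weights are supported by row/column scaling (the weighted problem is solved
exactly, not approximately).

`bootstrap_maps()` case-resamples records (the resampling unit is the whole
record), collapses duplicated draws to unique points with multiplicity
weights, refits with per-replicate GCV, and predicts every in-mask pixel
(cell centres; elevation from the DEM band). Per pixel it reports the
replicate mean, the 2.5/97.5 percentile bounds, and the bootstrap SD
(`pooled_se`); per replicate the in-sample r² and the out-of-bag MSPE.
Replicate b is seeded from `seed + b`, so ensembles are bit-reproducible.

A caveat stated plainly: a case resample contains no pure error (duplicated
records carry identical responses), so per-replicate GCV tends toward light
smoothing. In-sample r² is consequently near 1 and should be read as a
resample statistic; the out-of-bag MSPE is the honest accuracy figure. The
light smoothing also widens the percentile intervals in data-dense regions,
which makes the downstream overlap test conservative — in our operating
characteristic simulations (B = 100, 400 records per period, a planted
shift of 15 units in half the range) the no-change half shows under 10%
falsely significant pixels while the planted shift is recovered within a
few percent. Percentile intervals do not correct smoothing bias; coverage
of the true surface degrades on strongly curved surfaces, which is why the
package's coverage simulation uses a gently curved surface and reports the
mean over three independent realizations.

`change_map()` applies the disjoint-interval rule per pixel: significant
where `[lo_pre, hi_pre]` and `[lo_post, hi_post]` are disjoint, zero change
otherwise, and also emits `sqrt(se_pre^2 + se_post^2)` — the pooled SE of a
difference of independently estimated surfaces — for downstream weighting.

# Change-vs-climate GLS

`sample_change_points()` draws n = 484 cells (the size of the smallest trait
dataset) uniformly without replacement from valid cells, one shared draw for
all responses. `fit_change_gls()` then fits, by ML,

    delta_trait ~ N(X beta, sigma2 W^(-1/2) C(rho) W^(-1/2)),

where `X` holds polynomial terms of the *raw* proportional changes (they are
already relative to pre-cutoff levels, so no re-centring), `C` is the
exponential correlogram over (lon, lat), and `W = diag(weight)` encodes
per-point precision. The default weight is `1 / pooled_se^2` (variance
weighting, normalized to mean 1); `weight_mode = "inverse_se"` gives the
`1/se` alternative reading. `sigma2` is profiled and `log rho` optimized by
Brent from four starting intervals. `enumerate_and_average()` fits the 11
marginality-respecting candidates over {F, F², P, P², F:P} (quadratics
imply their linear term, the interaction implies both linear terms,
intercept always included) and averages the `delta AICc <= 2` set exactly as
the historic models do.

# Numerical and procedural choices

* Half-open cells `[west, east) x [south, north)`: every in-extent point
  maps to exactly one cell; a record maps to the decade containing its year.
* Sample SD (n−1) everywhere a variable is centred and scaled; the
  transform is an object that can be applied to new data.
* Exact 1-D 2-means for the breeding-season split (sorted-split enumeration
  minimizing within-cluster sum of squares): deterministic and
  permutation-invariant, no initialization seeds. A band is split only with
  >= 4 records and a centre gap above 45 days (a reproducible stand-in for
  visual histogram inspection); the earlier cluster is breeding, because
  explosive breeders are collected early in the season. Nonbreeding records
  leave the phenology analyses only; size analyses keep them.
* Leap years are honoured in Julian-day conversion (dates are the raw data).
* AICc with `n <= k + 1` is a domain error, never silently NA.
* Optimizer tolerances: function tolerance 1e-10, up to 400 Nelder–Mead
  iterations per start; non-convergence is a flag on the fit, and flagged
  fits are excluded from averaging sets with a warning.

# Simulation study sizes

The package's verification simulations (test suite and acceptance script)
use: 100 replicates at n = 680 records for mixed-model recovery; 100
replicates at 484 points for change-GLS recovery (planted quadratic surface
with spatially correlated noise, SD 0.1 response units, range 0.3°); 50
replicates for sign-pattern recovery with noise at 20% of the planted
signal's SD — chosen so the planted terms are about as strongly significant
as the benchmark coefficients they mirror; B = 100 bootstrap replicates and
400 records per period for change-detection operating characteristics. The
end-to-end pipeline example runs on a reduced grid with B in the tens purely
as a smoke test; its statistical behaviour is covered by the targeted
simulations above.

# Known limitations

* No REML option (model comparison requires ML; the variance components are
  therefore slightly biased downward at small n).
* No random slopes, no nugget effect, no anisotropy in the correlogram.
* GCV is evaluated on a fixed grid (quarter-decade resolution in
  log-lambda), not continuously optimized.
* The CI-overlap change rule is conservative by construction (two disjoint
  95% intervals correspond to a much smaller pairwise alpha); it trades
  power for robustness to uneven sampling, which is exactly its purpose
  here.
* Proportional change is undefined where the pre-period mean is zero; such
  cells are masked and counted, which matters for variables that can
  plausibly hit zero (FFD in extreme climates).
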