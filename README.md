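# traitshift

Spatially explicit analysis of body-size and breeding-phenology shifts under
climate change, built for century-scale, continent-scale natural history
collection data.

Widespread ectotherms such as the wood frog carry strong latitudinal and
elevational clines in body size (snout–vent length, SVL) and breeding date
(Julian day of collection, a sound proxy in explosive breeders). This
package implements a three-stage analysis of how such traits relate to
climate and how they changed after the onset of rapid warming:

1. **Historic climate–trait models** (pre-cutoff, default 1960). Linear
   mixed models fit by maximum likelihood:

   `y ~ N(Xβ, V)`, `V = σ²_year ZZ' + σ²_resid C(ρ)`, `C(ρ)_ij = exp(−d_ij/ρ)`

   with a collection-year random intercept and exponential spatial residual
   correlation over each record's (latitude, longitude, elevation). Five
   candidate fixed-effect sets over frost-free days (FFD), precipitation,
   and their interaction are ranked by AICc; the ΔAICc ≤ 2 set is
   full-averaged with unconditional SEs, and marginal/conditional R² are
   reported from the variance decomposition.
2. **Bootstrap thin-plate-spline trait maps.** Per period, 100 case
   resamples each fit a 3-D thin-plate spline (kernel φ(r) = −r, affine
   null space, GCV smoothing) of the trait on (lat, lon, elev) and predict
   every 5-arc-minute pixel in the range mask. Pixels whose pre- and
   post-period 95% percentile intervals are disjoint are significant change;
   everywhere else change is zero.
3. **Change-vs-climate GLS.** At 484 random points, trait change is
   regressed on second-order polynomials of *proportional* climate change
   (Δ/pre-cutoff level) by ML GLS with exponential spatial correlation and
   per-point precision weights `1/pooled_se²` from the mapping stage; all 11
   marginality-respecting polynomial models are enumerated, ranked by AICc
   and averaged.

A first-class synthetic-data module (`synth_params()`,
`gen_climate_stack()`, `gen_specimens()`) generates climate grids and
specimen records with the exact statistical structure the stages assume —
correlated temperature/FFD fields (target r = 0.87), trait clines, year
random intercepts, spatially correlated residuals, nonbreeding-season
contaminant dates, a spatially uneven post-cutoff warming shift — with full
ground truth, so every estimator is verifiable end to end without any
external data. Collection-date filtering uses exact (enumerative) 1-D
2-means per degree of latitude to separate breeding from nonbreeding
collections.

## Worked example

```r
library(traitshift)

# the t statistic of a correlation of .873 on 1,262 df
pearson_t(0.873, 1262)
#> 63.58771

# synthetic pre-warming records with a planted FFD effect on breeding date
p  <- synth_params(n_records = c(pre = 300, post = 0),
                   contaminant_frac = 0, seed = 11)
st <- gen_climate_stack(p)
gs <- gen_specimens(p, st)
rc <- record_climate(gs$specimens, st)

fits <- fit_candidates(rc$records, "julian_day", coords = c("lat", "lon"),
                       n_starts = 2)
select_and_average(fits)
#> <model_selection> best: ffd | averaged over: ffd, ffd*precip
#>        model loglik k aicc   delta    weight converged
#> 1        ffd  -1251 5 2512   0.000 5.675e-01      TRUE
#> 2 ffd*precip  -1250 7 2514   1.791 2.318e-01      TRUE
#> 3 ffd+precip  -1251 6 2514   2.079 2.007e-01      TRUE
#> 4          1  -1305 4 2619 106.796 3.660e-24      TRUE
#> 5     precip  -1305 5 2621 108.589 1.493e-24      TRUE
#>          term estimate     se    lower   upper significant
#> 1 (Intercept) 146.3515 5.7512 135.0791 157.624        TRUE
#> 2         ffd -42.0375 2.9949 -47.9075 -36.167        TRUE
#> 3      precip   0.1180 0.5053  -0.8723   1.108       FALSE
#> 4  ffd:precip   0.5859 0.9773  -1.3296   2.501       FALSE
```

The generator planted a slope of −42.4 days per SD of FFD; model selection
puts essentially all Akaike weight on FFD-containing models and the averaged
estimate (−42.0, CI −47.9 to −36.2) recovers the truth, while the
precipitation terms are correctly flagged non-significant.

The full pipeline — simulate/ingest, season filter, historic models, maps,
change GLS, manifest — runs from one config:

```r
man <- run_pipeline(pipeline_config(out_dir = "run1", seed = 1))
```

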