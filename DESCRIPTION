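Package: traitshift
Title: Spatially Explicit Analysis of Body-Size and Phenology Shifts Under
    Climate Change
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying spatially explicit shifts in body size and
    breeding phenology of widespread species from georeferenced natural history
    collections and decadal climate rasters. Fits climate-trait linear mixed
    models with a collection-year random intercept and exponential spatial
    residual correlation by maximum likelihood, performs AICc model selection
    and full model averaging, builds bootstrap thin-plate-spline trait maps
    pre and post a warming cutoff with per-pixel confidence intervals, detects
    significant change via confidence-interval overlap, and regresses trait
    change on proportional climate change with pooled-SE-weighted spatially
    correlated generalized least squares. A synthetic-data module generates
    specimen records and climate grids with known ground truth so every stage
    is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    nlme
Config/testthat/edition: 3
RoxygenNote: 7.3.3
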