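# change-point sets with planted polynomial structure on real generated
# proportional-change fields
ts_change_setup <- function(n = 484, seed = 77) {
  st <- ts_default_stack()
  pc <- proportional_change(st, 1960)
  chg <- structure(list(grid = st$grid, mask = st$mask,
                        delta = pc$prop_change$ffd * 0,
                        significant = st$mask,
                        delta_masked = pc$prop_change$ffd * 0,
                        pooled_se = matrix(1, st$grid$nrow, st$grid$ncol)),
                   class = "change_map")
  pts <- sample_change_points(chg, pc, n = n, seed = seed)
  pts$pooled_se <- abs(0.8 + 0.4 * scale(pts$lat)[, 1]^2)
  pts$weight <- 1 / pts$pooled_se^2
  pts$weight <- pts$weight / mean(pts$weight)
  pts
}

ts_plant_delta <- function(pts, beta, sigma, rho = 0.3, seed = 1) {
  f <- pts$prop_dffd; p <- pts$prop_dprecip
  sig <- beta[1] * f + beta[2] * f^2 + beta[3] * p + beta[4] * p^2 +
    beta[5] * f * p
  D <- as.matrix(dist(cbind(pts$lon, pts$lat)))
  L <- chol(exp(-D / rho) + diag(1e-8, nrow(pts)))
  set.seed(seed)
  pts$delta_trait <- sig + sigma * pts$pooled_se *
    drop(crossprod(L, rnorm(nrow(pts))))
  pts
}

test_that("point sampling is deterministic, in-mask and duplicate-free", {
  st <- ts_default_stack()
  pc <- proportional_change(st, 1960)
  chg <- structure(list(grid = st$grid, mask = st$mask,
                        delta = pc$prop_change$ffd * 0,
                        significant = st$mask,
                        delta_masked = pc$prop_change$ffd * 0,
                        pooled_se = matrix(1, st$grid$nrow, st$grid$ncol)),
                   class = "change_map")
  p1 <- sample_change_points(chg, pc, n = 484, seed = 9)
  p2 <- sample_change_points(chg, pc, n = 484, seed = 9)
  expect_identical(p1, p2)
  expect_equal(nrow(p1), 484)
  expect_equal(anyDuplicated(p1[, c("row", "col")]), 0L)
  ij <- cell_index(st$grid, p1$lon, p1$lat)
  expect_true(all(st$mask[cbind(ij$row, ij$col)]))
  expect_false(identical(sample_change_points(chg, pc, n = 484, seed = 10),
                         p1))
  # asking for more points than valid cells names the shortfall
  expect_error(sample_change_points(chg, pc, n = sum(st$mask) + 1,
                                    seed = 1), "valid cells")
})

test_that("exactly-n valid cells are selected exhaustively for any seed", {
  st <- ts_default_stack()
  pc <- proportional_change(st, 1960)
  keep <- which(st$mask & is.finite(pc$prop_change$ffd))[1:50]
  m <- matrix(NA_real_, st$grid$nrow, st$grid$ncol)
  m[keep] <- 0
  chg <- structure(list(grid = st$grid, mask = st$mask, delta = m,
                        significant = st$mask, delta_masked = m,
                        pooled_se = m + 1),
                   class = "change_map")
  pA <- sample_change_points(chg, pc, n = 50, seed = 1)
  pB <- sample_change_points(chg, pc, n = 50, seed = 999)
  expect_identical(pA[, c("row", "col")], pB[, c("row", "col")])
})

test_that("marginality violations and singular designs are errors", {
  pts <- ts_change_setup(n = 100)
  pts$delta_trait <- rnorm(100)
  expect_error(fit_change_gls(pts, c("F2")), "linear term")
  expect_error(fit_change_gls(pts, c("F", "P2")), "linear term")
  expect_error(fit_change_gls(pts, c("F", "F:P")), "both linear terms")
  pts2 <- pts
  pts2$prop_dprecip <- pts2$prop_dffd        # collinear climate change
  expect_error(fit_change_gls(pts2, c("F", "P")), "collinear")
})

test_that("with equal weights and tiny range the fit reduces to OLS", {
  pts <- ts_change_setup(n = 120)
  pts$pooled_se <- 1
  pts$weight <- 1
  set.seed(5)
  pts$delta_trait <- 3 + 10 * pts$prop_dffd - 4 * pts$prop_dprecip +
    rnorm(120, 0, 0.3)   # iid noise: ML should drive rho to the boundary
  fit <- fit_change_gls(pts, c("F", "P"))
  ols <- coef(lm(delta_trait ~ prop_dffd + prop_dprecip, data = pts))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 0.02)
})

test_that("estimates and intervals scale with the response", {
  pts <- ts_change_setup(n = 150)
  pts <- ts_plant_delta(pts, c(20, -70, 10, 8, -90), sigma = 0.1, seed = 4)
  f1 <- fit_change_gls(pts, c("F", "F2", "P"))
  pts2 <- pts
  pts2$delta_trait <- 10 * pts$delta_trait
  f2 <- fit_change_gls(pts2, c("F", "F2", "P"))
  expect_equal(unname(f2$beta), unname(10 * f1$beta), tolerance = 1e-4)
  expect_equal(unname(f2$lower), unname(10 * f1$lower), tolerance = 1e-3)
  expect_equal(f2$significant, f1$significant)
})

test_that("the candidate enumeration respects marginality and averages", {
  cand <- gls_candidate_terms()
  expect_length(cand, 11)
  for (tt in cand) {
    if ("F2" %in% tt) expect_true("F" %in% tt)
    if ("P2" %in% tt) expect_true("P" %in% tt)
    if ("F:P" %in% tt) expect_true(all(c("F", "P") %in% tt))
  }
  pts <- ts_change_setup(n = 150)
  pts <- ts_plant_delta(pts, c(25, -80, 0, 0, 0), sigma = 0.05, seed = 6)
  ea <- enumerate_and_average(pts)
  expect_s3_class(ea$selection, "model_selection")
  expect_length(ea$failed, 0)
  # strong {F, F2} signal: the top model contains both terms
  top <- ea$fits[[ea$selection$best]]
  expect_true(all(c("F", "F2") %in% top$fixed_terms))
  # singleton support set reproduces that model's estimates
  if (length(ea$selection$support) == 1) {
    av <- ea$selection$averaged
    bm <- ea$fits[[ea$selection$support]]
    for (tm in names(bm$beta))
      expect_equal(av$estimate[av$term == tm], unname(bm$beta[tm]))
  }
})

test_that("inflating one point's SE dampens its influence smoothly", {
  pts <- ts_change_setup(n = 120)
  pts <- ts_plant_delta(pts, c(20, -70, 10, 8, -90), sigma = 0.15, seed = 8)
  # equal-weight baseline with one gross outlier so influence is visible
  pts$pooled_se <- rep(1, nrow(pts))
  pts$weight <- rep(1, nrow(pts))
  pts$delta_trait[1] <- pts$delta_trait[1] + 5
  base <- fit_change_gls(pts, c("F", "P"))$beta
  infl <- pts
  infl$pooled_se[1] <- 100
  infl$weight <- 1 / infl$pooled_se^2
  infl$weight <- infl$weight / mean(infl$weight)
  up <- fit_change_gls(infl, c("F", "P"))$beta
  dropped <- fit_change_gls(pts[-1, ], c("F", "P"))$beta
  # down-weighting caps the point's pull: the shift it leaves behind is no
  # larger (up to optimizer jitter) than outright removal, never amplified
  tol <- 0.05 * abs(dropped - base) + 1e-6
  expect_true(all(abs(up - base) <= abs(dropped - base) + tol))
})

test_that("a planted (-F, +F2) phenology response has an interior minimum", {
  pts <- ts_change_setup(n = 200)
  pts <- ts_plant_delta(pts, c(-500, 4000, 0, 0, 0), sigma = 0.2, seed = 12)
  ea <- enumerate_and_average(pts)
  est <- setNames(ea$selection$averaged$estimate, ea$selection$averaged$term)
  expect_lt(est[["F"]], 0)
  expect_gt(est[["F2"]], 0)
  vertex <- -est[["F"]] / (2 * est[["F2"]])
  expect_gt(vertex, min(pts$prop_dffd))
  expect_lt(vertex, max(pts$prop_dffd))
})

test_that("partial-effect curves evaluate the averaged polynomial", {
  pts <- ts_change_setup(n = 150)
  pts <- ts_plant_delta(pts, c(20, -70, 10, 8, -90), sigma = 0.1, seed = 3)
  ea <- enumerate_and_average(pts)
  pe <- partial_effects(ea$selection, pts, axis = "F")
  expect_equal(sort(unique(pe$conditioning)), c("high", "low", "median"))
  est <- setNames(ea$selection$averaged$estimate, ea$selection$averaged$term)
  co <- function(nm) if (nm %in% names(est)) est[[nm]] else 0
  i <- 7
  row <- pe[i, ]
  expected <- co("(Intercept)") + co("F") * row$x + co("F2") * row$x^2 +
    co("P") * row$cond_value + co("P2") * row$cond_value^2 +
    co("F:P") * row$x * row$cond_value
  expect_equal(row$fitted, expected)
})

test_that("the equal-weight fit matches an independent ML GLS route", {
  pts <- ts_change_setup(n = 150, seed = 77)
  pts$pooled_se <- 1
  pts$weight <- 1
  f <- pts$prop_dffd
  D <- as.matrix(dist(cbind(pts$lon, pts$lat)))
  set.seed(9)
  L <- chol(exp(-D / 0.4) + diag(1e-8, 150))
  pts$delta_trait <- 2 + 15 * f - 50 * f^2 + 5 * pts$prop_dprecip +
    0.2 * drop(crossprod(L, rnorm(150)))
  mine <- fit_change_gls(pts, c("F", "F2", "P"))
  ref <- nlme::gls(delta_trait ~ prop_dffd + I(prop_dffd^2) + prop_dprecip,
                   data = pts, correlation = nlme::corExp(form = ~ lon + lat),
                   method = "ML")
  expect_equal(unname(mine$beta), unname(coef(ref)), tolerance = 1e-5)
  expect_equal(unname(mine$rho),
               unname(coef(ref$modelStruct$corStruct,
                           unconstrained = FALSE)), tolerance = 1e-4)
  expect_equal(mine$loglik, as.numeric(logLik(ref)), tolerance = 1e-6)
})
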