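# small synthetic mixed-model dataset with known structure
ts_lmm_data <- function(n = 60, beta = c(3.8, 0.05, 0.1), s2y = 0.02^2,
                        s2r = 0.1^2, rho = 0.8, seed = 1, years = 8) {
  set.seed(seed)
  d <- data.frame(lat = runif(n, 40, 44), lon = runif(n, -84, -80),
                  elev_m = runif(n, 100, 1200),
                  year = sample(1901:(1900 + years), n, replace = TRUE),
                  sex = "female",
                  scaled_ffd = rnorm(n), scaled_precip = rnorm(n))
  u <- rnorm(years, 0, sqrt(s2y)); names(u) <- 1901:(1900 + years)
  D <- as.matrix(dist(cbind(d$lat, d$lon)))
  L <- chol(exp(-D / rho) + diag(1e-8, n))
  e <- drop(crossprod(L, rnorm(n))) * sqrt(s2r)
  mu <- beta[1] + beta[2] * d$scaled_ffd + beta[3] * d$scaled_precip
  d$svl_mm <- exp(mu + u[as.character(d$year)] + e)
  d$julian_day <- 100 + 5 * d$scaled_ffd + rnorm(n, 0, 3)
  d
}

test_that("the likelihood equals an independent dense evaluation", {
  d <- ts_lmm_data(n = 60, seed = 3)
  y <- log(d$svl_mm)
  X <- cbind(1, d$scaled_ffd, d$scaled_precip)
  co <- cbind(d$lat, d$lon)
  for (par in list(c(0.02^2, 0.1^2, 0.8), c(0.001, 0.05, 2.5))) {
    got <- lmm_loglik(y, X, d$year, co, beta = c(3.8, 0.05, 0.1),
                      sigma2_year = par[1], sigma2_resid = par[2],
                      rho = par[3])
    want <- ts_dense_loglik(y, X, d$year, co, c(3.8, 0.05, 0.1),
                            par[1], par[2], par[3])
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("the optimizer attains the brute-force grid maximum", {
  d <- ts_lmm_data(n = 50, seed = 11)
  fit <- fit_lmm(d, "log_svl_female", c("ffd", "precip"),
                 coords = c("lat", "lon"))
  y <- log(d$svl_mm)
  X <- cbind(1, d$scaled_ffd, d$scaled_precip)
  co <- cbind(d$lat, d$lon)
  # dense grid over the variance components; beta profiled by GLS per node
  grid_best <- -Inf
  for (lg in seq(-6, 2, length.out = 9))
    for (lr in seq(log(0.05), log(5), length.out = 9))
      for (ls in seq(log(0.002), log(0.05), length.out = 7)) {
        s2r <- exp(ls); s2y <- exp(lg) * s2r; rho <- exp(lr)
        Vm <- s2y * (outer(d$year, d$year, `==`) + 0) +
          s2r * (exp(-as.matrix(dist(co)) / rho) + diag(1e-8, nrow(d)))
        b <- solve(t(X) %*% solve(Vm, X), t(X) %*% solve(Vm, y))
        ll <- ts_dense_loglik(y, X, d$year, co, b, s2y, s2r, rho)
        if (ll > grid_best) grid_best <- ll
      }
  expect_gte(fit$loglik, grid_best - 1e-4)
})

test_that("with negligible random structure the GLS solution is OLS", {
  set.seed(21)
  d <- ts_lmm_data(n = 80, s2y = 0, rho = 0.8, seed = 21)
  # iid response: overwrite with pure OLS structure
  d$svl_mm <- exp(3.8 + 0.05 * d$scaled_ffd + rnorm(80, 0, 0.05))
  fit <- fit_lmm(d, "log_svl_female", "ffd", coords = c("lat", "lon"))
  ols <- coef(lm(log(svl_mm) ~ scaled_ffd, data = d))
  expect_equal(unname(fit$beta), unname(ols), tolerance = 0.01)
})

test_that("AICc arithmetic, limit and monotone penalty", {
  expect_equal(aicc(-50, 3, 20), 107.5)
  expect_equal(aicc(-50, 3, 1e8), -2 * -50 + 6, tolerance = 1e-6)
  expect_lt(aicc(-50, 3, 20), aicc(-50, 4, 20))
  expect_error(aicc(-50, 19, 20), "n > k")
})

test_that("the candidate set has five admissible members", {
  ct <- candidate_terms()
  expect_length(ct, 5)
  expect_equal(ct[["1"]], character(0))
  expect_equal(ct[["ffd*precip"]], c("ffd", "precip", "ffd:precip"))
  expect_error(lmm_design(data.frame(scaled_ffd = 1, scaled_precip = 1),
                          "ffd:precip"), "requires both main effects")
})

test_that("model averaging: weights, singleton and equal-weight cases", {
  mk <- function(aicc, beta, se, terms) {
    structure(list(aicc = aicc, loglik = -aicc / 2, k = length(beta) + 3,
                   n = 100, beta = beta, se_beta = se, converged = TRUE,
                   fixed_terms = terms), class = "lmm_fit")
  }
  f1 <- mk(100, c("(Intercept)" = 1, ffd = 0.4),
           c("(Intercept)" = 0.1, ffd = 0.1), "ffd")
  f2 <- mk(100, c("(Intercept)" = 1), c("(Intercept)" = 0.1), character(0))
  f3 <- mk(130, c("(Intercept)" = 0), c("(Intercept)" = 1), "precip")
  sel <- select_and_average(list(a = f1, b = f2, c = f3))
  expect_equal(sum(sel$table$weight), 1, tolerance = 1e-12)
  # equal AICc: term present in one of two models halves under full averaging
  av <- sel$averaged
  expect_equal(av$estimate[av$term == "ffd"], 0.2)
  # singleton support set equals that model's estimates
  f4 <- mk(90, c("(Intercept)" = 2, precip = 1),
           c("(Intercept)" = 0.2, precip = 0.2), "precip")
  sel2 <- select_and_average(list(a = f1, b = f2, d = f4))
  expect_equal(sel2$support, "d")
  expect_equal(sel2$averaged$estimate[sel2$averaged$term == "precip"], 1)
  expect_true(sel2$averaged$significant[sel2$averaged$term == "precip"])
})

test_that("marginal and conditional R2 behave at the limits", {
  d <- ts_lmm_data(n = 60, seed = 5)
  f0 <- fit_lmm(d, "log_svl_female", character(0), coords = c("lat", "lon"))
  expect_equal(unname(r2_nakagawa(f0)["r2_marginal"]), 0)
  f1 <- fit_lmm(d, "log_svl_female", c("ffd", "precip"),
                coords = c("lat", "lon"))
  r2 <- r2_nakagawa(f1)
  expect_gte(r2[["r2_conditional"]], r2[["r2_marginal"]])
  expect_lte(r2[["r2_conditional"]], 1)
})

test_that("likelihood ratio test matches the chi-square reference", {
  d <- ts_lmm_data(n = 60, seed = 7)
  full <- fit_lmm(d, "log_svl_female", c("ffd", "precip"),
                  coords = c("lat", "lon"))
  red <- fit_lmm(d, "log_svl_female", "ffd", coords = c("lat", "lon"))
  out <- lrt(full, red)
  expect_equal(unname(out["chi2"]),
               max(0, 2 * (full$loglik - red$loglik)))
  expect_equal(unname(out["df"]), 1)
  # the 5% critical value of chi-square(1) is 3.841
  expect_equal(pchisq(3.841, 1, lower.tail = FALSE), 0.05, tolerance = 1e-3)
  self <- lrt(full, full)
  expect_equal(unname(self["chi2"]), 0)
  expect_equal(unname(self["p"]), 1)
  expect_error(lrt(red, full), "not nested")
})

test_that("response rescaling scales estimates and keeps significance", {
  d <- ts_lmm_data(n = 70, seed = 9)
  f1 <- fit_lmm(d, "julian_day", "ffd", coords = c("lat", "lon"))
  d2 <- d
  d2$julian_day <- d$julian_day * 10
  f2 <- fit_lmm(d2, "julian_day", "ffd", coords = c("lat", "lon"))
  expect_equal(unname(f2$beta), unname(10 * f1$beta), tolerance = 1e-3)
  expect_equal(unname(f2$se_beta), unname(10 * f1$se_beta),
               tolerance = 1e-2)
  s1 <- abs(f1$beta / f1$se_beta) > 1.96
  s2 <- abs(f2$beta / f2$se_beta) > 1.96
  expect_equal(s2, s1)
})

test_that("selection flags the planted negative FFD-phenology slope", {
  # pre-period style data with a negative FFD effect on Julian day
  st <- ts_default_stack()
  hits <- 0
  nrep <- 10
  for (r in seq_len(nrep)) {
    p <- synth_params(n_records = c(pre = 350, post = 0),
                      contaminant_frac = 0, seed = 400 + r)
    gs <- gen_specimens(p, st)
    d <- gs$specimens
    d$scaled_ffd <- gs$truth$climate$scaled_ffd
    d$scaled_precip <- gs$truth$climate$scaled_precip
    fits <- fit_candidates(d, "julian_day", coords = c("lat", "lon"),
                           n_starts = 2)
    sel <- select_and_average(fits)
    row <- sel$averaged[sel$averaged$term == "ffd", ]
    if (nrow(row) == 1 && row$significant && row$estimate < 0)
      hits <- hits + 1
  }
  expect_gte(hits / nrep, 0.95)
})
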